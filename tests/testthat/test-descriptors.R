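# Descriptor engine, cleaning, correlation-threshold selection and
# standardization.

toy_dm <- function(values) {
  structure(list(values = values,
                 valid_mask = matrix(TRUE, nrow(values), ncol(values),
                                     dimnames = dimnames(values)),
                 engine = list(name = "toy", version = "0"),
                 dropped = character()),
            class = "descriptor_matrix")
}

test_that("hydrogen-bond donor counts come out under the nHBDon name", {
  dm <- compute_descriptors(compound_set(
    c("c1ccc2c(c1)cc[nH]2", "c1ccccc1", "NCCc1c[nH]c2ccccc12",
      "Oc1ccccc1O")))
  expect_identical(nrow(dm$values), 4L)
  expect_equal(unname(dm$values[, "nHBDon"]), c(1, 0, 2, 2))
  expect_true(all(c("nHBDon", "MW", "TPSA") %in% colnames(dm$values)))
})

test_that("cleaning drops constant and incomplete columns and is idempotent", {
  v <- cbind(good = c(1, 2, 3), const = c(3, 3, 3),
             holed = c(1, NA, 2))
  dm <- toy_dm(v)
  dm$valid_mask[2, "holed"] <- FALSE
  cl <- clean_descriptors(dm)
  expect_identical(colnames(cl$values), "good")
  expect_setequal(cl$dropped, c("const", "holed"))
  expect_identical(clean_descriptors(cl)$values, cl$values)
  expect_error(clean_descriptors(toy_dm(cbind(k = c(1, 1, 1)))),
               "no usable descriptors")
})

test_that("correlation filter matches hand-computed Pearson r", {
  v <- cbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1), C = c(1, 1, 2, 1))
  sel <- correlation_filter(toy_dm(v), c(1, 2, 3, 4), 0.39)
  expect_setequal(attr(sel, "selected_names"), c("A", "B"))
  expect_equal(sel$r[sel$name == "A"], 1)
  expect_equal(sel$r[sel$name == "B"], -1)
  expect_equal(sel$r[sel$name == "C"], 0.2581989, tolerance = 1e-6)
  expect_error(correlation_filter(toy_dm(v[1:2, ]), c(1, 2), 0.5),
               "at least 3")
  # threshold 0 selects everything
  expect_identical(sum(correlation_filter(toy_dm(v), 1:4, 0)$selected), 3L)
})

test_that("Pearson r agrees with the textbook sum formula to 1e-12", {
  set.seed(77)
  for (rep in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    dm <- toy_dm(cbind(x = x))
    r_pkg <- correlation_filter(dm, y, 0)$r
    n <- length(x)
    r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    expect_equal(r_pkg, r_hand, tolerance = 1e-12)
  }
})

test_that("selection is nested: higher thresholds select subsets", {
  dm <- planted_descriptors()
  y <- planted_set()$activity_pct
  prev <- colnames(dm$values)
  ths <- c(0, 0.25, 0.39, 0.6, 0.9)
  n_prev <- Inf
  for (t in ths) {
    sel <- attr(correlation_filter(dm, y, t), "selected_names")
    expect_true(all(sel %in% prev), info = paste("threshold", t))
    expect_lte(length(sel), n_prev)
    prev <- sel; n_prev <- length(sel)
  }
})

test_that("standardization uses training statistics only", {
  v <- cbind(d = c(1, 2, 3, 10))
  dm <- toy_dm(v)
  std <- standardize_descriptors(dm, "d", train_rows = 1:3)
  expect_equal(mean(std$values[1:3, "d"]), 0)
  expect_equal(sd(std$values[1:3, "d"]), 1)
  # a test value equal to the training mean maps to 0
  v2 <- cbind(d = c(1, 2, 3, 2))
  std2 <- standardize_descriptors(toy_dm(v2), "d", train_rows = 1:3)
  expect_equal(unname(std2$values[4, "d"]), 0)
  # non-idempotence: re-applying the same statistics shifts again
  twice <- sweep(sweep(std$values, 2, attr(std, "center")), 2,
                 attr(std, "scale"), "/")
  expect_false(isTRUE(all.equal(twice, std$values)))
  expect_error(standardize_descriptors(toy_dm(cbind(d = c(5, 5, 5, 1))),
                                       "d", 1:3), "zero training")
})

test_that("engine failures mask rows instead of aborting", {
  eng <- descriptor_engine()
  broken <- eng
  broken$fn <- function(smiles) {
    out <- eng$fn(smiles)
    out[1, ] <- NA_real_
    out
  }
  dm <- compute_descriptors(compound_set(c("CCO", "CCC", "CCCC")),
                            engine = broken)
  expect_false(any(dm$valid_mask[1, ]))
  expect_true(all(dm$valid_mask[2:3, ]))
})
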