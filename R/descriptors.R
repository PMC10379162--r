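# Molecular descriptors behind a pluggable engine, plus the cleaning and
# correlation-threshold feature selection used by the QSAR stage.

#' Descriptor engines
#'
#' An engine is a named list with `name`, `version` and `fn(smiles)`
#' returning a numeric data.frame (one row per molecule, NA on failure).
#' The bundled `"openbabel"` engine combines Open Babel properties
#' (hydrogen-bond donor count exposed under the conventional descriptor
#' name `nHBDon`, plus MW, logP, TPSA, MR, acceptor counts, fluorine
#' count) with topological counts computed from the kekulized molecular
#' graph (atom/ring/aromatic counts).
#'
#' @param name engine name; only `"openbabel"` is bundled.
#' @return an engine object.
#' @export
descriptor_engine <- function(name = "openbabel") {
  if (name != "openbabel")
    stop("unknown descriptor engine: ", name)
  version <- tryCatch(
    as.character(utils::packageVersion("ChemmineOB")),
    error = function(e) "unknown")
  list(name = "openbabel", version = version, fn = function(smiles) {
    props <- ob_properties(smiles)
    out <- data.frame(
      nHBDon = props$HBD, nHBAcc = props$HBA2, MW = props$MW,
      SLogP = props$logP, TPSA = props$TPSA, MR = props$MR,
      nF = props$nF)
    topo <- t(vapply(smiles, function(s) {
      tryCatch({
        g <- parse_smiles(kekulize_smiles(s))
        el <- g$atoms$element
        c(nHeavyAtom = nrow(g$atoms),
          nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
          nRing = nrow(g$bonds) - nrow(g$atoms) + 1L,
          nBondsD = sum(g$bonds$order == 2L))
      }, error = function(e) rep(NA_real_, 6L))
    }, numeric(6), USE.NAMES = FALSE))
    colnames(topo) <- c("nHeavyAtom", "nC", "nN", "nO", "nRing",
                        "nBondsD")
    cbind(out, as.data.frame(topo))
  })
}

#' Compute a descriptor matrix for a compound set
#'
#' @param records a [compound_set()].
#' @param engine a [descriptor_engine()].
#' @return object of class `descriptor_matrix`: `values` (numeric matrix,
#'   compounds x descriptors, rownames = compound ids), `valid_mask`
#'   (same shape, FALSE where the engine failed), `engine` (name and
#'   version), `dropped` (names removed by [clean_descriptors()], empty
#'   here).
#' @examples
#' \donttest{
#' dm <- compute_descriptors(compound_set("c1ccc2c(c1)cc[nH]2"))
#' dm$values[, "nHBDon"]  # 1: the pyrrole N-H
#' }
#' @export
compute_descriptors <- function(records, engine = descriptor_engine()) {
  stopifnot(inherits(records, "compound_set"))
  vals <- engine$fn(records$smiles)
  m <- as.matrix(vals)
  rownames(m) <- records$id
  if (anyDuplicated(colnames(m)))
    stop("descriptor engine returned duplicate column names")
  structure(list(values = m, valid_mask = is.finite(m),
                 engine = list(name = engine$name,
                               version = engine$version),
                 dropped = character()),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("<descriptor_matrix> ", nrow(x$values), " compounds x ",
      ncol(x$values), " descriptors (engine ", x$engine$name, " ",
      x$engine$version, ")",
      if (length(x$dropped)) paste0("; ", length(x$dropped), " dropped"),
      "\n", sep = "")
  invisible(x)
}

#' Drop unusable descriptor columns
#'
#' Removes columns with any missing/non-finite entry and columns with
#' zero variance (their correlation with the target is undefined).
#' Idempotent; the names removed accumulate in `$dropped`.
#'
#' @param dm a [compute_descriptors()] result.
#' @return a cleaned `descriptor_matrix`.
#' @export
clean_descriptors <- function(dm) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  m <- dm$values
  ok <- apply(dm$valid_mask, 2L, all) & apply(m, 2L, function(col)
    all(is.finite(col)) && stats::sd(col) > 0)
  if (!any(ok)) stop("no usable descriptors after cleaning")
  structure(list(values = m[, ok, drop = FALSE],
                 valid_mask = dm$valid_mask[, ok, drop = FALSE],
                 engine = dm$engine,
                 dropped = c(dm$dropped, colnames(m)[!ok])),
            class = "descriptor_matrix")
}

#' Correlation-threshold feature selection
#'
#' Selects descriptors whose absolute Pearson correlation with the
#' measured activity reaches the threshold (inclusive). Raising the
#' threshold can only shrink the selection, which is how the QSAR stage
#' trades model complexity against fit.
#'
#' @param dm a cleaned [descriptor_matrix()].
#' @param activities numeric activities aligned with the rows of `dm`.
#' @param threshold correlation threshold in `[0, 1]`.
#' @param rows optional row indices to compute correlations on (training
#'   rows only, to avoid test leakage); default all rows.
#' @return object of class `feature_selection`: data.frame with `name`,
#'   `r`, `selected`, plus attributes `threshold` and `selected_names`.
#' @examples
#' # toy: y correlates perfectly with A, negatively with B, weakly with C
#' dm <- structure(list(
#'   values = cbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1),
#'                  C = c(1, 1, 2, 1)),
#'   valid_mask = matrix(TRUE, 4, 3), engine = list(name = "toy",
#'   version = "0"), dropped = character()), class = "descriptor_matrix")
#' sel <- correlation_filter(dm, c(1, 2, 3, 4), 0.39)
#' attr(sel, "selected_names")  # A and B
#' @export
correlation_filter <- function(dm, activities, threshold, rows = NULL) {
  stopifnot(inherits(dm, "descriptor_matrix"),
            threshold >= 0, threshold <= 1)
  m <- dm$values
  if (is.null(rows)) rows <- seq_len(nrow(m))
  stopifnot(length(activities) == nrow(m))
  if (length(rows) < 3L)
    stop("correlation filtering needs at least 3 compounds")
  y <- activities[rows]
  r <- apply(m[rows, , drop = FALSE], 2L, function(col) {
    if (stats::sd(col) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(col, y)
  })
  selected <- !is.na(r) & abs(r) >= threshold
  out <- data.frame(name = colnames(m), r = as.numeric(r),
                    selected = selected, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, threshold = threshold,
            selected_names = colnames(m)[selected],
            class = c("feature_selection", "data.frame"))
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> threshold ", attr(x, "threshold"), ": ",
      sum(x$selected), " of ", nrow(x), " descriptors selected\n",
      sep = "")
  NextMethod()
}

#' Standardize selected descriptors with training-row statistics
#'
#' Centers and scales the selected columns by the mean and standard
#' deviation of the *training rows only*, applied identically to all
#' rows, so no information leaks from the test partition.
#'
#' @param dm a cleaned [descriptor_matrix()].
#' @param selection a [correlation_filter()] result (or character vector
#'   of column names).
#' @param train_rows indices of the training rows.
#' @return a `descriptor_matrix` restricted to the selected columns with
#'   standardized values; attributes `center` and `scale` carry the
#'   training statistics.
#' @export
standardize_descriptors <- function(dm, selection, train_rows) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  cols <- if (is.character(selection)) selection
          else attr(selection, "selected_names")
  stopifnot(all(cols %in% colnames(dm$values)))
  m <- dm$values[, cols, drop = FALSE]
  ctr <- colMeans(m[train_rows, , drop = FALSE])
  scl <- apply(m[train_rows, , drop = FALSE], 2L, stats::sd)
  if (any(scl == 0))
    stop("zero training-set standard deviation in: ",
         paste(cols[scl == 0], collapse = ", "),
         " (should have been removed by clean_descriptors)")
  std <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  out <- structure(list(values = std,
                        valid_mask = dm$valid_mask[, cols, drop = FALSE],
                        engine = dm$engine, dropped = dm$dropped),
                   class = "descriptor_matrix")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Write a feature-selection report
#'
#' @param selection a [correlation_filter()] result.
#' @param path output CSV path (columns name, r, selected).
#' @export
write_selection_report <- function(selection, path) {
  utils::write.csv(as.data.frame(selection), path, row.names = FALSE)
  invisible(path)
}

#' Write a descriptor table
#'
#' @param dm a [descriptor_matrix()].
#' @param path output CSV path (compounds x descriptors).
#' @export
write_descriptor_table <- function(dm, path) {
  utils::write.csv(data.frame(id = rownames(dm$values), dm$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
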