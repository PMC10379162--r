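# Thin wrappers around Open Babel (via ChemmineOB). All chemistry-toolkit
# plumbing -- canonical SMILES, kekulization, molecular properties, path
# fingerprints -- funnels through this file so the rest of the package is
# toolkit-agnostic.

# Run one Open Babel conversion over newline-separated SMILES input.
# `out_opts` are output-format options (e.g. "k" = kekule SMILES), which
# ChemmineOB::convertFormat cannot set (it only passes GENOPTIONS), so we
# drive the low-level OBConversion bindings directly.
ob_convert <- function(smiles, to = "CAN", out_opts = character()) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character())
  # Tag each input with an index so silently-dropped invalid molecules can
  # be detected and mapped back to their positions.
  src <- paste(paste0(smiles, "\tx", seq_along(smiles)), collapse = "\n")
  in_str <- ChemmineOB:::istreamFromString(src)
  out_str <- ChemmineOB:::ostreamToString()
  conv <- ChemmineOB:::OBConversion(in_str, out_str)
  if (!ChemmineOB:::OBConversion_SetInAndOutFormats(conv, "SMI", to))
    stop("Open Babel cannot convert SMI -> ", to)
  for (opt in out_opts)
    ChemmineOB:::OBConversion_AddOption(conv, opt, "OUTOPTIONS", "")
  ChemmineOB:::OBConversion_Convert(conv)
  raw <- ChemmineOB:::stringFromOstream(out_str)
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  out <- rep(NA_character_, length(smiles))
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    idx <- suppressWarnings(as.integer(sub("^x", "", trimws(parts[2]))))
    if (!is.na(idx)) out[idx] <- trimws(parts[1])
  }
  out[!nzchar(out)] <- NA_character_
  out
}

#' Canonicalize SMILES strings
#'
#' Maps every SMILES of a molecule to the toolkit's unique canonical form,
#' the key used throughout the package for deduplication and novelty checks.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize(c("C1=CC2=C(C=C1)C=CN2", "c1ccc2c(c1)cc[nH]2"))
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  bad <- is.na(smiles) | !nzchar(trimws(smiles))
  if (any(bad))
    stop("cannot canonicalize empty SMILES at position(s) ",
         paste(which(bad), collapse = ", "))
  out <- suppressWarnings(ob_convert(smiles, to = "CAN"))
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop("unparseable SMILES: '", smiles[i], "'")
  }
  out
}

# Kekulized SMILES: aromatic rings written with alternating single/double
# bonds, atom order preserved (not canonicalized), so distinct enumerated
# representations stay distinct. The SELFIES codec and the graph layer
# operate on kekule structures only.
kekulize_smiles <- function(smiles) {
  out <- suppressWarnings(ob_convert(smiles, to = "SMI", out_opts = "k"))
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop("unparseable SMILES: '", smiles[i], "'")
  }
  out
}

# TRUE for every string Open Babel parses to a non-empty molecule.
is_valid_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(logical())
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (any(ok)) {
    res <- suppressWarnings(ob_convert(smiles[ok], to = "CAN"))
    ok[ok] <- !is.na(res)
  }
  ok
}

# Molecular properties from Open Babel (MW, logP, TPSA, HBD, HBA1, HBA2,
# MR, nF). Returns a data.frame with one row per molecule; NA rows for
# failures.
ob_properties <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste(smiles, collapse = "\n"),
                                 identity)
  props <- lapply(mols, function(m) {
    tryCatch(ChemmineOB::prop_OB(m), error = function(e) NULL)
  })
  cols <- c("MW", "logP", "TPSA", "HBD", "HBA1", "HBA2", "MR", "nF")
  out <- as.data.frame(matrix(NA_real_, nrow = length(smiles),
                              ncol = length(cols)))
  names(out) <- cols
  for (i in seq_along(props)) {
    p <- props[[i]]
    if (is.null(p) || i > length(smiles)) next
    for (cn in cols)
      if (!is.null(p[[cn]])) out[i, cn] <- as.numeric(p[[cn]])
  }
  out
}

# Open Babel FP2 path fingerprint (native 1024 bits), optionally folded.
ob_fingerprint_bits <- function(smiles, nbits = 1024L) {
  if (length(smiles) == 0L) return(list())
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste(smiles, collapse = "\n"),
                                 identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "FP2")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  native <- ncol(fp)
  lapply(seq_len(nrow(fp)), function(i) {
    bits <- which(fp[i, ] != 0) - 1L
    if (nbits < native) bits <- sort(unique(bits %% nbits))
    bits
  })
}
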