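#' The fixed 97-descriptor panel
#'
#' Returns the names of the 97 2D physicochemical descriptors used
#' throughout the package, in their fixed canonical order: molecular
#' connectivity (Chi) and shape (Kappa) indices, E-state and partial-charge
#' (PEOE), refractivity (SMR) and lipophilicity (SlogP) van der Waals
#' surface-area bins, Wildman-Crippen logP/MR, hydrogen-bonding and ring
#' counts, TPSA, and related size descriptors. All descriptor matrices in
#' the package keep their columns in this order so that files are
#' bit-comparable across runs.
#'
#' @return Character vector of length 97.
#' @export
#' @examples
#' length(descriptor_names())
descriptor_names <- function() {
  c(
    "Chi0", "Chi0n", "Chi0v", "Chi1", "Chi1n", "Chi1v", "Chi2n", "Chi2v",
    "Chi3n", "Chi3v", "Chi4n", "Chi4v", "EState_VSA1", "EState_VSA10",
    "EState_VSA11", "EState_VSA2", "EState_VSA3", "EState_VSA4",
    "EState_VSA5", "EState_VSA6", "EState_VSA7", "EState_VSA8",
    "EState_VSA9", "FractionCSP3", "HallKierAlpha", "HeavyAtomCount",
    "Ipc", "Kappa1", "Kappa2", "Kappa3", "LabuteASA", "MolLogP", "MolMR",
    "MolWt", "NHOHCount", "NOCount", "NumAliphaticCarbocycles",
    "NumAliphaticHeterocycles", "NumAliphaticRings",
    "NumAromaticCarbocycles", "NumAromaticHeterocycles",
    "NumAromaticRings", "NumHAcceptors", "NumHDonors", "NumHeteroatoms",
    "NumRotatableBonds", "NumSaturatedCarbocycles",
    "NumSaturatedHeterocycles", "NumSaturatedRings", "PEOE_VSA1",
    "PEOE_VSA10", "PEOE_VSA11", "PEOE_VSA12", "PEOE_VSA13", "PEOE_VSA14",
    "PEOE_VSA2", "PEOE_VSA3", "PEOE_VSA4", "PEOE_VSA5", "PEOE_VSA6",
    "PEOE_VSA7", "PEOE_VSA8", "PEOE_VSA9", "RingCount", "SMR_VSA1",
    "SMR_VSA10", "SMR_VSA2", "SMR_VSA3", "SMR_VSA4", "SMR_VSA5",
    "SMR_VSA6", "SMR_VSA7", "SMR_VSA8", "SMR_VSA9", "SlogP_VSA1",
    "SlogP_VSA10", "SlogP_VSA11", "SlogP_VSA12", "SlogP_VSA2",
    "SlogP_VSA3", "SlogP_VSA4", "SlogP_VSA5", "SlogP_VSA6", "SlogP_VSA7",
    "SlogP_VSA8", "SlogP_VSA9", "TPSA", "VSA_EState1", "VSA_EState10",
    "VSA_EState2", "VSA_EState3", "VSA_EState4", "VSA_EState5",
    "VSA_EState6", "VSA_EState7", "VSA_EState8", "VSA_EState9"
  )
}

.lysoacc_env <- new.env(parent = emptyenv())

rdkit_script <- function() {
  path <- system.file("python", "rdkit_tools.py", package = "lysoacc")
  if (!nzchar(path)) {
    # during development (pkgload) the inst/ prefix is present
    path <- system.file("inst", "python", "rdkit_tools.py", package = "lysoacc")
  }
  if (!nzchar(path)) stop("rdkit_tools.py helper not found in package", call. = FALSE)
  path
}

#' Check availability of the RDKit chemistry backend
#'
#' Descriptor computation and structure standardization are delegated to
#' RDKit through the `python` interpreter on the PATH. This checks (once
#' per session) that the interpreter can import RDKit.
#'
#' @return `TRUE` or `FALSE`, with the RDKit version in attribute
#'   `"version"` when available.
#' @export
rdkit_available <- function() {
  if (!is.null(.lysoacc_env$rdkit_ok)) return(.lysoacc_env$rdkit_ok)
  ver <- tryCatch(
    suppressWarnings(system2("python", c(shQuote(rdkit_script()), "version"),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character()
  )
  ok <- length(ver) >= 1L && nzchar(ver[[1L]])
  if (ok) attr(ok, "version") <- ver[[1L]]
  .lysoacc_env$rdkit_ok <- ok
  ok
}

rdkit_run <- function(mode, compound_id, smiles) {
  if (!isTRUE(as.logical(rdkit_available()))) {
    stop("the RDKit chemistry backend is not available (cannot import rdkit ",
         "through `python`)", call. = FALSE)
  }
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  utils::write.csv(
    data.frame(compound_id = compound_id, smiles = smiles,
               stringsAsFactors = FALSE),
    infile, row.names = FALSE
  )
  status <- system2("python", c(shQuote(rdkit_script()), mode,
                                "--infile", shQuote(infile),
                                "--outfile", shQuote(outfile)))
  if (!identical(status, 0L)) {
    stop("RDKit helper exited with status ", status, call. = FALSE)
  }
  out <- utils::read.csv(outfile, stringsAsFactors = FALSE,
                         colClasses = c(compound_id = "character"))
  out$error[is.na(out$error)] <- ""
  bad <- nzchar(out$error)
  if (any(bad)) {
    stop("structure processing failed for compound(s) ",
         paste0(out$compound_id[bad], " (", out$error[bad], ")",
                collapse = "; "),
         call. = FALSE)
  }
  out$error <- NULL
  out
}

#' Standardize molecular structures
#'
#' Produces the standardized 2D parent structure used for descriptor
#' computation: the largest organic fragment is kept (desalting),
#' protonation states are neutralized, and the canonical tautomer is
#' selected. The operation is idempotent: standardizing an already
#' standardized structure returns it unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @param compound_id Optional identifiers used in error messages
#'   (defaults to names of `smiles` or the position).
#' @return Character vector of canonical standardized SMILES, same length
#'   as the input.
#' @export
#' @examples
#' \dontrun{
#' standardize_structure("CC(=O)[O-].[Na+]")  # -> "CC(=O)O"
#' }
standardize_structure <- function(smiles, compound_id = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(compound_id)) {
    compound_id <- if (!is.null(names(smiles))) names(smiles) else
      as.character(seq_along(smiles))
  }
  if (anyDuplicated(compound_id)) {
    stop("duplicate compound_id values: ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "),
         call. = FALSE)
  }
  out <- rdkit_run("standardize", compound_id, smiles)
  stats::setNames(out$smiles, compound_id)
}

#' Compute the 97-descriptor panel
#'
#' Evaluates the full 97-descriptor panel (see [descriptor_names()]) for
#' each input structure. Structures are expected to already be
#' standardized (see [standardize_structure()]); the computation itself is
#' deterministic and purely 2D (no conformers are generated).
#'
#' @inheritParams standardize_structure
#' @return Numeric matrix with one row per structure and 97 named columns
#'   in the fixed panel order; row names are the compound identifiers.
#'   The RDKit version is attached as attribute `"rdkit_version"`.
#' @export
compute_descriptors <- function(smiles, compound_id = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(compound_id)) {
    compound_id <- if (!is.null(names(smiles))) names(smiles) else
      as.character(seq_along(smiles))
  }
  if (anyDuplicated(compound_id)) {
    stop("duplicate compound_id values: ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "),
         call. = FALSE)
  }
  out <- rdkit_run("descriptors", compound_id, smiles)
  mat <- as.matrix(out[, descriptor_names(), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- out$compound_id
  if (!all(is.finite(mat))) {
    bad <- rownames(mat)[!apply(is.finite(mat), 1L, all)]
    stop("non-finite descriptor values for compound(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(mat, "rdkit_version") <- attr(rdkit_available(), "version")
  mat
}

#' Build an aligned descriptor table from compound records
#'
#' Standardizes every structure, computes the 97-descriptor panel, and
#' returns a single table whose rows align with the input order, with the
#' optional measurement and label columns carried alongside. The
#' operation is fail-fast: any unparseable structure aborts the whole
#' table with the offending identifiers named.
#'
#' @param records Data frame with columns `compound_id` and `smiles`, and
#'   optionally `ie_ratio` (nonnegative intracellular/extracellular
#'   concentration ratio), `acc_class` and `ltr_class` (integer 1-5) and
#'   `set_label` (`"training"`/`"validation"`). Missing labels are `NA`.
#' @return Data frame: `compound_id`, the 97 descriptor columns in fixed
#'   order, then `ie_ratio`, `acc_class`, `ltr_class`, `set_label`.
#' @export
build_descriptor_table <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (!all(c("compound_id", "smiles") %in% names(records))) {
    stop("records must have columns compound_id and smiles", call. = FALSE)
  }
  id <- as.character(records$compound_id)
  if (anyDuplicated(id)) {
    stop("duplicate compound_id values: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  check_class_column(records$acc_class, "acc_class")
  check_class_column(records$ltr_class, "ltr_class")
  if (!is.null(records$ie_ratio) &&
      any(records$ie_ratio < 0, na.rm = TRUE)) {
    stop("ie_ratio must be nonnegative", call. = FALSE)
  }
  std <- standardize_structure(records$smiles, id)
  desc <- compute_descriptors(unname(std), id)
  out <- data.frame(compound_id = id, desc, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  n <- nrow(out)
  out$ie_ratio <- if (is.null(records$ie_ratio)) rep(NA_real_, n) else
    as.numeric(records$ie_ratio)
  out$acc_class <- if (is.null(records$acc_class)) rep(NA_integer_, n) else
    as.integer(records$acc_class)
  out$ltr_class <- if (is.null(records$ltr_class)) rep(NA_integer_, n) else
    as.integer(records$ltr_class)
  out$set_label <- if (is.null(records$set_label)) rep(NA_character_, n) else
    as.character(records$set_label)
  attr(out, "rdkit_version") <- attr(desc, "rdkit_version")
  out
}

check_class_column <- function(x, what) {
  if (is.null(x)) return(invisible(NULL))
  bad <- !is.na(x) & !(x %in% 1:5)
  if (any(bad)) {
    stop(what, " values must be integers in 1..5", call. = FALSE)
  }
  invisible(NULL)
}

#' Read compound records from a SMILES or CSV file
#'
#' A `.smi`/`.smiles` file holds one record per line: the SMILES string,
#' whitespace, then the identifier. A CSV file must have columns
#' `compound_id` and `smiles` and may carry `ie_ratio`, `acc_class`,
#' `ltr_class` and `set_label`.
#'
#' @param path File path.
#' @return Data frame of compound records.
#' @export
read_compounds <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.(smi|smiles)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    id <- vapply(parts, function(p)
      if (length(p) >= 2L) p[[2L]] else NA_character_, "")
    if (anyNA(id)) id[is.na(id)] <- paste0("cpd", which(is.na(id)))
    return(data.frame(compound_id = id, smiles = smiles,
                      stringsAsFactors = FALSE))
  }
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(compound_id = "character"))
  if (!all(c("compound_id", "smiles") %in% names(out))) {
    stop("CSV must have columns compound_id and smiles", call. = FALSE)
  }
  out
}

#' Write a descriptor table to CSV
#'
#' Columns are written in the canonical order (`compound_id`, the 97
#' descriptors, labels); missing labels become empty fields. Output is
#' byte-identical across runs for identical input.
#'
#' @param table Data frame as produced by [build_descriptor_table()] or
#'   [lyso_simulate()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  front <- intersect(c("compound_id", descriptor_names(),
                       "ie_ratio", "acc_class", "ltr_class", "set_label"),
                     names(table))
  rest <- setdiff(names(table), front)
  utils::write.csv(table[, c(front, rest), drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}
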