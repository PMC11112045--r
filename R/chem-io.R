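#' Molecule set container
#'
#' A `molecule_set` bundles compound identifiers, SMILES, a numeric target
#' matrix (one column per task), a logical mask of observed labels, and a
#' split tag per molecule (`"train"`, `"valid"`, `"test"` or `"unassigned"`).
#' Masked target cells are never read by any loss or metric.
#'
#' @param id character vector of stable identifiers.
#' @param smiles character vector of SMILES strings (already validated).
#' @param targets numeric matrix, one row per molecule, one column per task.
#' @param target_mask logical matrix of the same shape as `targets`; `TRUE`
#'   marks an observed label.
#' @param split character vector of split tags.
#' @return An object of class `molecule_set`.
#' @export
molecule_set <- function(id, smiles, targets, target_mask = NULL,
                         split = NULL) {
  targets <- as.matrix(targets)
  n <- length(smiles)
  if (length(id) != n || nrow(targets) != n) {
    stop_input("id, smiles and targets must describe the same molecules")
  }
  if (ncol(targets) < 1L) stop_input("at least one target column is required")
  if (is.null(target_mask)) target_mask <- !is.na(targets)
  target_mask <- as.matrix(target_mask)
  if (!identical(dim(target_mask), dim(targets))) {
    stop_input("targets and target_mask must have identical dimensions")
  }
  split <- split %||% rep("unassigned", n)
  split <- match.arg(split, c("train", "valid", "test", "unassigned"),
                     several.ok = TRUE)
  if (length(split) == 1L) split <- rep(split, n)
  if (is.null(colnames(targets))) {
    colnames(targets) <- paste0("task", seq_len(ncol(targets)))
  }
  colnames(target_mask) <- colnames(targets)
  structure(
    list(id = as.character(id), smiles = as.character(smiles),
         targets = targets, target_mask = target_mask, split = split),
    class = "molecule_set"
  )
}

#' @export
length.molecule_set <- function(x) length(x$smiles)

#' @export
`[.molecule_set` <- function(x, i) {
  molecule_set(x$id[i], x$smiles[i], x$targets[i, , drop = FALSE],
               x$target_mask[i, , drop = FALSE], x$split[i])
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set> %d molecules, %d task(s)\n",
              length(x), ncol(x$targets)))
  cat("  split:", paste(sprintf("%s=%d", names(table(x$split)),
                                table(x$split)), collapse = " "), "\n")
  invisible(x)
}

n_tasks <- function(records) ncol(records$targets)

split_index <- function(records, split) which(records$split == split)

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Unparseable strings map to
#' `NA` (OpenBabel prints its own diagnostic on stderr).
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  ## Batch through OpenBabel, using the molfile title field to realign the
  ## output (invalid molecules are silently dropped from OB's output).
  tags <- paste0("m", seq_len(n))
  input <- paste0(smiles, " ", tags, "\n", collapse = "")
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", input),
                  error = function(e) "")
  res <- rep(NA_character_, n)
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines, "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2L) {
        idx <- match(p[[2]], tags)
        if (!is.na(idx)) res[idx] <- p[[1]]
      }
    }
  }
  ## OB can emit empty SMILES for junk input; treat as unparseable.
  res[!is.na(res) & !nzchar(res)] <- NA_character_
  ## a parse failure can abort the rest of the batch: retry missing
  ## entries one at a time before declaring them unparseable
  if (anyNA(res) && n > 1L) {
    for (i in which(is.na(res))) res[i] <- canonical_smiles(smiles[i])
  }
  res
}

#' Read a MoleculeNet-dialect CSV into a molecule set
#'
#' Expects a delimited text table with a header row, one SMILES column and
#' one or more numeric target columns. Blank target cells become masked
#' labels. Rows whose SMILES cannot be parsed are dropped with a counted
#' warning.
#'
#' @param path path to a comma- (default) or tab-delimited file.
#' @param smiles_column name of the SMILES column (default `"smiles"`).
#' @param target_columns character vector of target column names; defaults to
#'   every column other than the SMILES column.
#' @param id_column optional name of an identifier column; row numbers are
#'   used when absent.
#' @param delim field delimiter; sniffed from the header line when `NULL`.
#' @return A [molecule_set()].
#' @export
parse_dataset <- function(path, smiles_column = "smiles",
                          target_columns = NULL, id_column = NULL,
                          delim = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "", fill = TRUE,
                          na.strings = c("", "NA"))
  if (!smiles_column %in% names(df)) {
    stop_input(sprintf("SMILES column '%s' not found in %s",
                       smiles_column, path))
  }
  if (is.null(target_columns)) {
    target_columns <- setdiff(names(df), c(smiles_column, id_column))
  }
  missing_cols <- setdiff(target_columns, names(df))
  if (length(missing_cols)) {
    stop_input("target column(s) not found: ",
               paste(missing_cols, collapse = ", "))
  }
  if (length(target_columns) < 1L) {
    stop_input("at least one target column is required")
  }
  smiles <- as.character(df[[smiles_column]])
  can <- canonical_smiles(smiles)
  bad <- is.na(can)
  if (any(bad)) {
    msg_log(sprintf("dropped %d row(s) with unparseable SMILES", sum(bad)))
  }
  if (all(bad)) stop_input("no parseable SMILES in ", path)
  keep <- which(!bad)
  targets <- as.matrix(df[keep, target_columns, drop = FALSE])
  storage.mode(targets) <- "double"
  rownames(targets) <- NULL
  ids <- if (!is.null(id_column)) as.character(df[[id_column]][keep]) else
    as.character(keep)
  molecule_set(ids, can[keep], targets)
}

#' Write a split manifest
#'
#' Records the id-to-split assignment of a molecule set as a two-column CSV
#' so a split can be reproduced or audited.
#'
#' @param records a [molecule_set()] with split assignments.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(records, path) {
  utils::write.csv(data.frame(id = records$id, split = records$split),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a molecule set as a MoleculeNet-dialect CSV
#'
#' @param records a [molecule_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  df <- data.frame(smiles = records$smiles, check.names = FALSE)
  tg <- records$targets
  tg[!records$target_mask] <- NA
  df <- cbind(df, as.data.frame(tg))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
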