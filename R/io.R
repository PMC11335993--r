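#' @importFrom utils read.delim write.table head
NULL

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "", ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Normalize protein/gene identifiers
#'
#' Case-folds identifiers to lower case and, when \code{stripIsoform} is
#' set, removes a trailing single-letter splice/isoform suffix (e.g.
#' \code{"unc-15a"} to \code{"unc-15"}). Identifier conventions differ
#' between deposited tables; matching across sets should go through one
#' normalization.
#'
#' @param ids character vector.
#' @param caseFold lower-case the identifiers (default TRUE).
#' @param stripIsoform drop a trailing isoform letter after a digit
#'   (default FALSE).
#' @return normalized character vector.
#' @examples
#' normalizeIds(c("HSP-6", "unc-15a"), stripIsoform = TRUE)
#' @export
normalizeIds <- function(ids, caseFold = TRUE, stripIsoform = FALSE) {
  ids <- as.character(ids)
  if (caseFold) ids <- tolower(ids)
  if (stripIsoform) ids <- sub("(?<=[0-9])[a-z]$", "", ids, perl = TRUE)
  ids
}

#' Read a paired quantification matrix from TSV
#'
#' Expects a tab-separated file with a \code{protein_id} column, a
#' \code{unique_peptides} column, and one column per sample named as a
#' \code{condition:pair} token (e.g. \code{case:1}, \code{control:1}).
#' Empty cells are parsed as missing values. Rows with duplicate protein
#' ids, negative intensities or unpaired samples are rejected.
#'
#' @param path file path.
#' @return An [InsolubleQuant-class].
#' @seealso [writeQuantMatrix()]
#' @export
readQuantMatrix <- function(path) {
  df <- .read_tsv(path)
  if (!"protein_id" %in% colnames(df)) stop("missing 'protein_id' column")
  if (!"unique_peptides" %in% colnames(df))
    stop("missing 'unique_peptides' column")
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup))
    stop("duplicate protein ids: ", paste(unique(dup), collapse = ", "))
  sampleCols <- grep("^(case|control):[0-9]+$", colnames(df), value = TRUE)
  if (!length(sampleCols)) stop("no sample columns of the form condition:pair")
  tok <- strsplit(sampleCols, ":", fixed = TRUE)
  condition <- vapply(tok, `[[`, "", 1)
  pair <- as.integer(vapply(tok, `[[`, "", 2))
  intensity <- as.matrix(df[, sampleCols, drop = FALSE])
  storage.mode(intensity) <- "double"
  if (any(intensity < 0, na.rm = TRUE)) stop("negative intensity values")
  rownames(intensity) <- df$protein_id
  InsolubleQuant(intensity, condition, pair,
                 as.integer(df$unique_peptides))
}

#' Write a quantification matrix to TSV
#'
#' Inverse of [readQuantMatrix()]; a written file reads back to an object
#' with identical content.
#'
#' @param x an [InsolubleQuant-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeQuantMatrix <- function(x, path) {
  m <- assay(x, "intensity")
  cd <- colData(x)
  df <- data.frame(protein_id = rownames(m),
                   unique_peptides = uniquePeptides(x),
                   stringsAsFactors = FALSE, check.names = FALSE)
  cols <- paste0(cd$condition, ":", cd$pair)
  for (j in seq_len(ncol(m))) df[[cols[j]]] <- m[, j]
  .write_tsv(df, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{term_id <tab> description <tab> member1 <tab> member2 ...}.
#' Members are de-duplicated within a term.
#'
#' @param path file path.
#' @param namespace annotation namespace tag stored on the collection.
#' @return A [GeneSets-class].
#' @export
readGmt <- function(path, namespace = "unspecified") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  GeneSets(sets, stats::setNames(desc, ids), namespace)
}

#' Write a GeneSets collection as GMT
#'
#' @param x a [GeneSets-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(x, path) {
  lines <- vapply(names(x), function(id) {
    paste(c(id, x@descriptions[[id]], x@sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease to GO-BP catalog from TSV
#'
#' Columns: \code{disease_id}, \code{name}, \code{category} (one of
#' [CARD_CATEGORIES] for age-related diseases, \code{non_ARD} otherwise),
#' \code{age_related} (TRUE/FALSE), \code{go_bp_terms}
#' (semicolon-separated GO-BP term ids). Reports the ARD / non-ARD counts
#' as a message.
#'
#' @param path file path.
#' @param quiet suppress the count message.
#' @return A [DiseaseBPCatalog-class].
#' @export
readDiseaseCatalog <- function(path, quiet = FALSE) {
  df <- .read_tsv(path)
  need <- c("disease_id", "name", "category", "age_related", "go_bp_terms")
  if (!all(need %in% colnames(df)))
    stop("disease catalog must have columns: ", paste(need, collapse = ", "))
  bad <- !(df$category %in% c(CARD_CATEGORIES, "non_ARD"))
  if (any(bad))
    stop("unknown category label: ",
         paste(unique(df$category[bad]), collapse = ", "))
  termSets <- strsplit(df$go_bp_terms, ";", fixed = TRUE)
  names(termSets) <- df$disease_id
  cat <- DiseaseBPCatalog(df[, need[1:4]], termSets)
  if (!quiet)
    message(sprintf("disease catalog: %d age-related, %d non-age-related",
                    length(ardIds(cat)), length(nardIds(cat))))
  cat
}

#' @rdname readDiseaseCatalog
#' @param x a [DiseaseBPCatalog-class].
#' @export
writeDiseaseCatalog <- function(x, path) {
  df <- diseaseInfo(x)
  df$go_bp_terms <- vapply(diseaseTerms(x)[df$disease_id],
                           paste, "", collapse = ";")
  .write_tsv(df, path)
  invisible(path)
}

#' Read a worm-to-human orthology map from two-column TSV
#'
#' Columns \code{worm_id}, \code{human_id}; one row per ortholog pair
#' (many-to-many allowed). Empty targets are rejected.
#'
#' @param path file path.
#' @return named list, worm id -> character vector of human ids.
#' @export
readOrthology <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (!all(c("worm_id", "human_id") %in% colnames(df)))
    stop("orthology map must have columns worm_id, human_id")
  if (any(is.na(df$human_id) | !nzchar(df$human_id)))
    stop("orthology rows with empty target identifier")
  lapply(split(df$human_id, df$worm_id), unique)
}

#' @rdname readOrthology
#' @param map named list as returned by \code{readOrthology}.
#' @export
writeOrthology <- function(map, path) {
  df <- data.frame(worm_id = rep(names(map), lengths(map)),
                   human_id = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a per-protein biophysical score table from TSV
#'
#' Columns: \code{protein_id} plus any of \code{camsol},
#' \code{zyggregator}, \code{catgranule}, \code{sigma_f}. Missing scores
#' are allowed per protein; non-positive supersaturation (\code{sigma_f})
#' values are rejected since the score is used on the log10 scale.
#'
#' @param path file path.
#' @return data.frame keyed by \code{protein_id}.
#' @export
readScoreTable <- function(path) {
  df <- .read_tsv(path)
  if (!"protein_id" %in% colnames(df)) stop("missing 'protein_id' column")
  if ("sigma_f" %in% colnames(df) && any(df$sigma_f <= 0, na.rm = TRUE))
    stop("sigma_f must be positive where present")
  df
}

#' @rdname readScoreTable
#' @param x score data.frame.
#' @export
writeScoreTable <- function(x, path) {
  .write_tsv(x, path)
  invisible(path)
}

#' Read a long-format expression series from TSV
#'
#' Columns \code{gene_id}, \code{age_day}, \code{value}, \code{dataset_id}.
#'
#' @param path file path.
#' @return data.frame in long format.
#' @export
readExpressionSeries <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "age_day", "value", "dataset_id")
  if (!all(need %in% colnames(df)))
    stop("expression series must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' @rdname readExpressionSeries
#' @param x expression data.frame.
#' @export
writeExpressionSeries <- function(x, path) {
  .write_tsv(x, path)
  invisible(path)
}

#' Read/write a protein set as a one-id-per-line text file
#'
#' @param path file path.
#' @param name set name (defaults to the file name).
#' @param provenance provenance note.
#' @return [readProteinSet()]: a [ProteinSet-class]; [writeProteinSet()]:
#'   \code{path}, invisibly.
#' @export
readProteinSet <- function(path, name = NULL, provenance = "") {
  ids <- readLines(path, warn = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (!nzchar(provenance)) provenance <- paste("read from", basename(path))
  proteinSet(name, ids, provenance)
}

#' @rdname readProteinSet
#' @param x a [ProteinSet-class].
#' @export
writeProteinSet <- function(x, path) {
  writeLines(members(x), path)
  invisible(path)
}
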