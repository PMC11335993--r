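#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' The five broad chronic age-related disease categories
#'
#' Category labels used to classify chronic age-related diseases (CARDs):
#' neurodegenerative, metabolic, cancer, cardiovascular and a catch-all
#' "other" class. Non-age-related diseases carry the pseudo-category
#' \code{"non_ARD"}.
#'
#' @export
CARD_CATEGORIES <- c("neurodegenerative", "metabolic", "cancer",
                     "cardiovascular", "other")

#' Paired insoluble-fraction quantification matrix
#'
#' An \code{InsolubleQuant} is a \linkS4class{SummarizedExperiment} holding
#' protein-level intensities (peak areas of extracted ion chromatograms)
#' from an SDS-insoluble fraction experiment with a paired case/control
#' design. Columns carry a \code{condition} ("case" or "control") and an
#' integer \code{pair} index; each pair index appears exactly once per
#' condition. Rows carry a \code{unique_peptides} count consumed by the
#' significance filter.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}; the single
#'   assay is named \code{"intensity"}.
#'
#' @seealso [InsolubleQuant()] for construction, [readQuantMatrix()] for
#'   reading from TSV, [pairedLogFoldChange()] for differential analysis.
#' @export
setClass("InsolubleQuant", contains = "SummarizedExperiment")

setValidity("InsolubleQuant", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  cd <- colData(object)
  if (!all(c("condition", "pair") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'condition' and 'pair'")
  else {
    if (!all(cd$condition %in% c("case", "control")))
      msg <- c(msg, "condition must be 'case' or 'control'")
    for (cond in c("case", "control")) {
      px <- cd$pair[cd$condition == cond]
      if (anyDuplicated(px))
        msg <- c(msg, sprintf("pair index duplicated within condition '%s'", cond))
    }
    if (!setequal(cd$pair[cd$condition == "case"],
                  cd$pair[cd$condition == "control"]))
      msg <- c(msg, "unpaired samples: case and control pair indices differ")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein identifiers (rownames) must be present and unique")
  if (!"unique_peptides" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'unique_peptides'")
  if ("intensity" %in% assayNames(object)) {
    x <- assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative where present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InsolubleQuant object
#'
#' @param intensity numeric matrix, proteins x samples; \code{NA} encodes a
#'   missing (undetected) value. Rownames are protein identifiers.
#' @param condition character vector over samples, \code{"case"} or
#'   \code{"control"}.
#' @param pair integer vector over samples; biological replicate (pairing)
#'   index. Each index must occur exactly once per condition.
#' @param uniquePeptides integer vector over proteins; number of unique
#'   peptides supporting each protein group.
#'
#' @return A validated [InsolubleQuant-class] object.
#' @examples
#' m <- matrix(c(10, 20, 11, 19), nrow = 1,
#'             dimnames = list("P1", NULL))
#' q <- InsolubleQuant(m, condition = c("case", "control", "case", "control"),
#'                     pair = c(1, 1, 2, 2), uniquePeptides = 3)
#' @export
InsolubleQuant <- function(intensity, condition, pair, uniquePeptides) {
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0(condition, ":", pair)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- paste0("protein", seq_len(nrow(intensity)))
  uniquePeptides <- rep_len(as.integer(uniquePeptides), nrow(intensity))
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = DataFrame(condition = as.character(condition),
                        pair = as.integer(pair),
                        row.names = colnames(intensity)),
    rowData = DataFrame(unique_peptides = uniquePeptides,
                        row.names = rownames(intensity)))
  new("InsolubleQuant", se)
}

#' @describeIn InsolubleQuant Number of unique peptides per protein group.
#' @param x an \code{InsolubleQuant}
#' @export
uniquePeptides <- function(x) rowData(x)$unique_peptides

#' Named protein identifier set with provenance
#'
#' A lightweight container for a named set of protein (or gene) identifiers
#' with a free-text provenance note, used for differential calls, published
#' insoluble proteomes, the aging core and the core insoluble proteome (CIP).
#'
#' @slot name single character, the set's name.
#' @slot members character vector of unique identifiers.
#' @slot provenance single character describing how the set was derived.
#' @export
setClass("ProteinSet",
         representation(name = "character", members = "character",
                        provenance = "character"),
         prototype(name = "set", members = character(), provenance = ""))

setValidity("ProteinSet", function(object) {
  if (anyDuplicated(object@members)) "members must be unique" else TRUE
})

#' Construct a ProteinSet
#'
#' @param name set name.
#' @param members identifier character vector (de-duplicated, NAs dropped).
#' @param provenance free-text provenance note.
#' @return A [ProteinSet-class].
#' @examples
#' proteinSet("cip", c("hsp-6", "unc-15"), "toy example")
#' @export
proteinSet <- function(name, members, provenance = "") {
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  new("ProteinSet", name = name, members = members,
      provenance = as.character(provenance)[1])
}

#' @describeIn proteinSet Accessor for the member identifiers.
#' @param x a \code{ProteinSet}
#' @export
members <- function(x) x@members

#' @describeIn proteinSet Accessor for the provenance note.
#' @export
provenance <- function(x) x@provenance

#' @export
setMethod("length", "ProteinSet", function(x) length(x@members))

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet '%s': %d members\n", object@name,
              length(object@members)))
  if (length(object@members))
    cat("  ", paste(utils::head(object@members, 6), collapse = ", "),
        if (length(object@members) > 6) ", ..." else "", "\n", sep = "")
  if (nzchar(object@provenance))
    cat("  provenance: ", object@provenance, "\n", sep = "")
})

#' Result of an exact protein-set overlap test
#'
#' Records the 2x2 overlap of two identifier sets within a stated universe
#' together with the exact hypergeometric (Fisher) tail probability and the
#' fold enrichment \eqn{k N / (a b)}.
#'
#' @slot nameA,nameB set names.
#' @slot a,b,k,N integer: |A|, |B|, |A intersect B|, universe size.
#' @slot pValue exact tail probability.
#' @slot foldEnrichment observed/expected overlap ratio.
#' @slot alternative "greater" (enrichment), "less" or "two.sided".
#' @seealso [fisherOverlap()]
#' @export
setClass("OverlapTest",
         representation(nameA = "character", nameB = "character",
                        a = "integer", b = "integer", k = "integer",
                        N = "integer", pValue = "numeric",
                        foldEnrichment = "numeric", alternative = "character"))

setValidity("OverlapTest", function(object) {
  msg <- character()
  if (object@k > min(object@a, object@b))
    msg <- c(msg, "k cannot exceed min(a, b)")
  if (object@a > object@N || object@b > object@N)
    msg <- c(msg, "set sizes cannot exceed the universe size")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn OverlapTest Exact tail probability of the overlap.
#' @param x an \code{OverlapTest}
#' @export
pValue <- function(x) x@pValue

#' @describeIn OverlapTest Fold enrichment of the observed overlap.
#' @export
foldEnrichment <- function(x) x@foldEnrichment

setMethod("show", "OverlapTest", function(object) {
  cat(sprintf("OverlapTest: '%s' (n=%d) vs '%s' (n=%d), universe N=%d\n",
              object@nameA, object@a, object@nameB, object@b, object@N))
  cat(sprintf("  overlap k=%d, fold enrichment=%.3g, p (%s)=%.3g\n",
              object@k, object@foldEnrichment, object@alternative,
              object@pValue))
})

#' Named collection of gene/term sets (GMT-style)
#'
#' Term-keyed membership sets within one annotation namespace (e.g. GO-BP,
#' KEGG), as parsed from a GMT file.
#'
#' @slot sets named list of character vectors (term id -> member ids).
#' @slot descriptions named character, term id -> human-readable name.
#' @slot namespace single character tag.
#' @seealso [readGmt()], [hypergeomEnrich()]
#' @export
setClass("GeneSets",
         representation(sets = "list", descriptions = "character",
                        namespace = "character"),
         prototype(sets = list(), descriptions = character(),
                   namespace = "unspecified"))

setValidity("GeneSets", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "term ids must be unique and named")
  if (any(lengths(object@sets) == 0))
    msg <- c(msg, "member sets must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSets collection
#'
#' @param sets named list of member identifier vectors (term id as name).
#' @param descriptions optional named character of term names.
#' @param namespace annotation namespace tag.
#' @return A [GeneSets-class].
#' @export
GeneSets <- function(sets, descriptions = NULL, namespace = "unspecified") {
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  new("GeneSets", sets = sets,
      descriptions = descriptions[names(sets)],
      namespace = namespace)
}

#' @export
setMethod("length", "GeneSets", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSets", function(x) names(x@sets))

#' @describeIn GeneSets The term-keyed list of member sets.
#' @param x a \code{GeneSets}
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSets", function(object) {
  cat(sprintf("GeneSets [%s]: %d terms, set sizes %d-%d\n",
              object@namespace, length(object@sets),
              if (length(object@sets)) min(lengths(object@sets)) else 0L,
              if (length(object@sets)) max(lengths(object@sets)) else 0L))
})

#' Disease to GO biological process catalog
#'
#' Maps diseases to the GO biological process terms implicated in their
#' genetic risk, with each disease flagged as chronic age-related (ARD) or
#' not and, for ARDs, classified into one of the five broad categories in
#' [CARD_CATEGORIES]. The reference catalog structure holds 38 ARDs over 5
#' categories plus 12 non-age-related diseases.
#'
#' @slot diseases data.frame with columns \code{disease_id}, \code{name},
#'   \code{category}, \code{age_related}.
#' @slot termSets named list (disease_id -> GO-BP term id set).
#' @seealso [readDiseaseCatalog()], [shareCounts()]
#' @export
setClass("DiseaseBPCatalog",
         representation(diseases = "data.frame", termSets = "list"))

setValidity("DiseaseBPCatalog", function(object) {
  msg <- character()
  d <- object@diseases
  need <- c("disease_id", "name", "category", "age_related")
  if (!all(need %in% colnames(d)))
    return(paste("diseases must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$disease_id))
    msg <- c(msg, "disease ids must be unique")
  bad <- d$age_related & !(d$category %in% CARD_CATEGORIES)
  if (any(bad))
    msg <- c(msg, paste("age-related diseases must carry one of the 5 broad",
                        "categories:", paste(d$disease_id[bad], collapse = ", ")))
  badn <- !d$age_related & d$category != "non_ARD"
  if (any(badn))
    msg <- c(msg, "non-age-related diseases must carry category 'non_ARD'")
  if (!setequal(names(object@termSets), d$disease_id))
    msg <- c(msg, "termSets must be keyed by the disease ids")
  if (any(lengths(object@termSets) == 0))
    msg <- c(msg, "disease term sets must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a DiseaseBPCatalog
#'
#' @param diseases data.frame with columns \code{disease_id}, \code{name},
#'   \code{category} (one of [CARD_CATEGORIES] for ARDs, \code{"non_ARD"}
#'   otherwise) and logical \code{age_related}.
#' @param termSets named list of GO-BP term id vectors, keyed by disease id.
#' @return A [DiseaseBPCatalog-class].
#' @export
DiseaseBPCatalog <- function(diseases, termSets) {
  diseases <- as.data.frame(diseases, stringsAsFactors = FALSE)
  termSets <- lapply(termSets, function(t) unique(as.character(t)))
  new("DiseaseBPCatalog", diseases = diseases,
      termSets = termSets[diseases$disease_id])
}

#' @describeIn DiseaseBPCatalog Disease ids of the age-related diseases.
#' @param x a \code{DiseaseBPCatalog}
#' @export
ardIds <- function(x) x@diseases$disease_id[x@diseases$age_related]

#' @describeIn DiseaseBPCatalog Disease ids of the non-age-related diseases.
#' @export
nardIds <- function(x) x@diseases$disease_id[!x@diseases$age_related]

#' @describeIn DiseaseBPCatalog The disease metadata table.
#' @export
diseaseInfo <- function(x) x@diseases

#' @describeIn DiseaseBPCatalog Disease-keyed GO-BP term sets.
#' @export
diseaseTerms <- function(x) x@termSets

#' @export
setMethod("length", "DiseaseBPCatalog", function(x) nrow(x@diseases))

setMethod("show", "DiseaseBPCatalog", function(object) {
  cat(sprintf("DiseaseBPCatalog: %d age-related + %d non-age-related diseases\n",
              length(ardIds(object)), length(nardIds(object))))
  tab <- table(object@diseases$category[object@diseases$age_related])
  cat("  ARD categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})
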