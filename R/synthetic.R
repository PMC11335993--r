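#' Simulate a paired insoluble-fraction quantification experiment
#'
#' Generates a protein x sample intensity matrix emulating a paired
#' case/control insoluble-fraction DIA experiment (default: 4 biological
#' replicate pairs, amyloid-expressing vs background-control animals) with a
#' spiked subset of truly insolubilising proteins of known log2 fold-change.
#' Intensities are lognormal: per-protein baseline log2 intensities are
#' normal, case samples of spiked proteins are multiplied by
#' \code{2^spikeLog2fc} before multiplicative noise, and values are then
#' masked completely at random at \code{missingRate}. Unique-peptide counts
#' are drawn from a unit-shifted Poisson so every protein has at least one
#' peptide.
#'
#' @param nProteins number of simulated protein groups.
#' @param nPairs number of biological replicate pairs (>= 2).
#' @param spikeFraction fraction of proteins given a true insolubility
#'   increase.
#' @param spikeLog2fc true case/control log2 fold-change of spiked proteins.
#' @param baselineLogMean,baselineLogSd mean and sd of baseline log2
#'   intensity across proteins.
#' @param noiseSd sd (log2 units) of the measurement noise on a per-pair
#'   case/control ratio; each sample contributes noise of sd
#'   \code{noiseSd/sqrt(2)} so that per-pair log2 differences have sd
#'   \code{noiseSd} around the true fold-change.
#' @param missingRate probability that any single measurement is missing.
#'   Protein-level DIA matrices after q-value sparse filtering are largely
#'   complete, hence the small default.
#' @param peptideCountMean mean unique-peptide count (>= 1); the default
#'   matches the study system's spectral library (about 5.5 peptides per
#'   protein group).
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return A list with elements \code{quant} (an [InsolubleQuant-class]) and
#'   \code{truth}: list with \code{spiked} (spiked protein ids) and
#'   \code{trueLog2fc} (named per-protein true log2 fold-change).
#' @examples
#' sim <- simulateQuantExperiment(nProteins = 50, spikeFraction = 0.1,
#'                                seed = 1)
#' length(sim$truth$spiked)
#' @export
simulateQuantExperiment <- function(nProteins = 2000, nPairs = 4,
                                    spikeFraction = 0.15, spikeLog2fc = 3,
                                    baselineLogMean = 17, baselineLogSd = 2,
                                    noiseSd = 0.25, missingRate = 0.01,
                                    peptideCountMean = 5.5, seed = 1) {
  stopifnot(is.finite(spikeLog2fc), is.finite(noiseSd),
            nPairs >= 2, nProteins >= 1,
            spikeFraction >= 0, spikeFraction <= 1,
            missingRate >= 0, missingRate <= 1,
            peptideCountMean >= 1)
  nSpike <- floor(spikeFraction * nProteins)
  if (spikeFraction > 0 && nSpike < 1) {
    warning("spikeFraction * nProteins < 1; no proteins spiked")
    nSpike <- 0L
  }
  old <- .Random.seed.exists()
  set.seed(as.integer(seed))
  on.exit(old(), add = TRUE)

  ids <- sprintf("prot%04d", seq_len(nProteins))
  spiked <- if (nSpike > 0) sort(sample(ids, nSpike)) else character()
  trueLfc <- stats::setNames(numeric(nProteins), ids)
  trueLfc[spiked] <- spikeLog2fc

  base <- stats::rnorm(nProteins, baselineLogMean, baselineLogSd)
  nSamp <- 2L * nPairs
  condition <- rep(c("case", "control"), each = nPairs)
  pair <- rep(seq_len(nPairs), times = 2)
  logI <- matrix(base, nProteins, nSamp)
  logI[, condition == "case"] <- logI[, condition == "case"] + trueLfc
  logI <- logI + matrix(stats::rnorm(nProteins * nSamp, 0,
                                     noiseSd / sqrt(2)),
                        nProteins, nSamp)
  intensity <- 2^logI
  if (missingRate > 0)
    intensity[matrix(stats::runif(nProteins * nSamp) < missingRate,
                     nProteins, nSamp)] <- NA_real_
  peptides <- 1L + stats::rpois(nProteins, peptideCountMean - 1)
  rownames(intensity) <- ids
  colnames(intensity) <- paste0(condition, ":", pair)
  quant <- InsolubleQuant(intensity, condition, pair, peptides)
  list(quant = quant,
       truth = list(spiked = spiked, trueLog2fc = trueLfc))
}

# save/restore .Random.seed so generators are pure in the caller's RNG stream
.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Simulate annotation, orthology and disease-BP catalog inputs
#'
#' Builds the input trio for the disease-sharing analysis with a planted
#' signal: a worm-to-human orthology map (1-to-k, k in 1..3), per-human-gene
#' GO-BP annotation sets, and a disease catalog in which each age-related
#' disease carries one of the five broad categories and a pool of GO-BP
#' terms. Proteins in \code{plantedSet} draw their annotation terms with the
#' weight of age-related disease pool terms multiplied by
#' \code{sharingBoost}, so at \code{sharingBoost = 1} planted and background
#' proteins are exchangeable.
#'
#' @param nProteins number of worm proteins to annotate (ids
#'   \code{prot0001}...), or a character vector of worm protein ids.
#' @param nTerms size of the GO-BP term vocabulary.
#' @param nDiseasesArd,nDiseasesNard number of age-related and
#'   non-age-related diseases (defaults 38 and 12, the reference catalog
#'   structure).
#' @param nCategories number of broad ARD categories (max 5).
#' @param plantedSet character vector of worm protein ids given boosted
#'   disease-term sharing; must be a subset of the protein ids.
#' @param sharingBoost multiplicative sampling weight (>= 1) on ARD-pool
#'   terms for planted proteins.
#' @param termsPerDisease,termsPerGene annotation set sizes.
#' @param seed integer seed.
#'
#' @return list with \code{annotations} (named list, human gene id -> GO-BP
#'   term ids), \code{orthology} (named list, worm id -> human ids),
#'   \code{catalog} (a [DiseaseBPCatalog-class]), and \code{truth} (list
#'   with \code{planted}).
#' @export
simulateAnnotationCatalog <- function(nProteins = 500, nTerms = 400,
                                      nDiseasesArd = 38, nDiseasesNard = 12,
                                      nCategories = 5,
                                      plantedSet = character(),
                                      sharingBoost = 1,
                                      termsPerDisease = 10, termsPerGene = 8,
                                      seed = 1) {
  if (nTerms < 1) stop("empty term vocabulary")
  stopifnot(sharingBoost >= 1, nCategories >= 1, nCategories <= 5)
  ids <- if (is.character(nProteins)) nProteins
         else sprintf("prot%04d", seq_len(nProteins))
  if (!all(plantedSet %in% ids))
    stop("plantedSet must be a subset of the protein identifiers")
  old <- .Random.seed.exists()
  set.seed(as.integer(seed))
  on.exit(old(), add = TRUE)

  terms <- sprintf("GO:%07d", seq_len(nTerms))
  # ARD diseases draw their pools from the first half of the vocabulary so
  # that boosting those terms concentrates planted proteins on ARD pools
  ardPoolTerms <- terms[seq_len(max(1, floor(nTerms / 2)))]
  catIdx <- rep_len(seq_len(nCategories), nDiseasesArd)
  diseases <- data.frame(
    disease_id = c(sprintf("ARD%02d", seq_len(nDiseasesArd)),
                   sprintf("NARD%02d", seq_len(nDiseasesNard))),
    name = c(sprintf("age-related disease %d", seq_len(nDiseasesArd)),
             sprintf("non-age-related disease %d", seq_len(nDiseasesNard))),
    category = c(CARD_CATEGORIES[catIdx], rep("non_ARD", nDiseasesNard)),
    age_related = rep(c(TRUE, FALSE), c(nDiseasesArd, nDiseasesNard)),
    stringsAsFactors = FALSE)
  termSets <- lapply(seq_len(nrow(diseases)), function(i) {
    pool <- if (diseases$age_related[i]) ardPoolTerms else terms
    sample(pool, min(termsPerDisease, length(pool)))
  })
  names(termSets) <- diseases$disease_id
  catalog <- DiseaseBPCatalog(diseases, termSets)

  # worm -> human orthology, 1-to-k with k in {1,2,3}
  k <- sample(1:3, length(ids), replace = TRUE)
  humanIds <- sprintf("HUM%05d", seq_len(sum(k)))
  orthology <- split(humanIds, factor(rep(seq_along(ids), k),
                                      levels = seq_along(ids)))
  names(orthology) <- ids

  ardUnion <- unique(unlist(termSets[diseases$age_related], use.names = FALSE))
  baseW <- rep(1, nTerms)
  names(baseW) <- terms
  boostW <- baseW
  boostW[ardUnion] <- sharingBoost
  annotations <- vector("list", length(humanIds))
  names(annotations) <- humanIds
  planted <- ids %in% plantedSet
  for (i in seq_along(ids)) {
    w <- if (planted[i]) boostW else baseW
    for (h in orthology[[i]])
      annotations[[h]] <- sample(terms, termsPerGene, prob = w)
  }
  list(annotations = annotations, orthology = orthology, catalog = catalog,
       truth = list(planted = plantedSet))
}

#' Simulate a per-protein biophysical score table
#'
#' Draws CamSol, Zyggregator and catGRANULE scores from normal location
#' families and supersaturation (sigma_f) values as lognormal (shifts applied
#' on the log10 scale), with per-set location shifts so that downstream
#' distribution comparisons have known ground truth. With a log10 shift
#' \code{s} on \code{sigma_f} and vanishing noise, the linear-scale mean
#' ratio of a shifted set over an unshifted one tends to \code{10^s}.
#'
#' @param sets named list of protein id vectors; sets may overlap but each
#'   protein receives its scores once, from the first set that contains it.
#' @param shifts named numeric, one per set: additive location shift for
#'   camsol/zyggregator/catgranule and log10-scale shift for sigma_f.
#'   Missing names default to 0.
#' @param noiseSd sd of the score distributions around their location.
#' @param sigmaFLog10Mean baseline mean of log10(sigma_f).
#' @param seed integer seed.
#'
#' @return data.frame with columns \code{protein_id}, \code{set},
#'   \code{camsol}, \code{zyggregator}, \code{catgranule}, \code{sigma_f}.
#' @export
simulateScoreTable <- function(sets, shifts = NULL, noiseSd = 1,
                               sigmaFLog10Mean = 0, seed = 1) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(shifts)) shifts <- stats::setNames(numeric(length(sets)),
                                                 names(sets))
  if (!all(names(shifts) %in% names(sets)))
    stop("unknown set identifier in shifts: ",
         paste(setdiff(names(shifts), names(sets)), collapse = ", "))
  if (!all(is.finite(shifts))) stop("shifts must be finite")
  full <- stats::setNames(numeric(length(sets)), names(sets))
  full[names(shifts)] <- shifts
  old <- .Random.seed.exists()
  set.seed(as.integer(seed))
  on.exit(old(), add = TRUE)

  seen <- character()
  out <- lapply(names(sets), function(s) {
    idsNew <- setdiff(unique(sets[[s]]), seen)
    seen <<- c(seen, idsNew)
    n <- length(idsNew)
    if (n == 0) return(NULL)
    data.frame(protein_id = idsNew, set = s,
               camsol = stats::rnorm(n, full[s], noiseSd),
               zyggregator = stats::rnorm(n, full[s], noiseSd),
               catgranule = stats::rnorm(n, full[s], noiseSd),
               sigma_f = 10^(stats::rnorm(n, sigmaFLog10Mean + full[s],
                                          noiseSd)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Simulate an aging expression time course
#'
#' Generates gene x age expression values over the given adult-day
#' timepoints (default days 2 to 10), with a planted fraction of genes given
#' a monotone linear mean trend (half increasing, half decreasing) and the
#' remainder flat, plus gaussian noise.
#'
#' @param nGenes number of genes.
#' @param timepoints strictly increasing numeric vector of adult ages
#'   (days); at least 3.
#' @param trendFraction fraction of genes with a planted trend.
#' @param trendSlope absolute mean expression change per day for planted
#'   genes.
#' @param noiseSd sd of measurement noise.
#' @param nDatasets replicate series per gene (independent datasets pooled
#'   downstream).
#' @param seed integer seed.
#'
#' @return list with \code{expr} (long data.frame: \code{gene_id},
#'   \code{age_day}, \code{value}, \code{dataset_id}) and \code{truth}
#'   (data.frame: \code{gene_id}, \code{trend} in -1/0/+1).
#' @export
simulateExpressionSeries <- function(nGenes = 300,
                                     timepoints = c(2, 4, 6, 8, 10),
                                     trendFraction = 0.1, trendSlope = 0.5,
                                     noiseSd = 0.3, nDatasets = 2, seed = 1) {
  if (length(timepoints) < 3) stop("fewer than 3 timepoints")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  stopifnot(trendFraction >= 0, trendFraction <= 1)
  old <- .Random.seed.exists()
  set.seed(as.integer(seed))
  on.exit(old(), add = TRUE)

  genes <- sprintf("gene%04d", seq_len(nGenes))
  nTrend <- floor(trendFraction * nGenes)
  trend <- integer(nGenes)
  if (nTrend > 0) {
    idx <- sample(nGenes, nTrend)
    trend[idx] <- rep_len(c(1L, -1L), nTrend)
  }
  nt <- length(timepoints)
  rows <- nGenes * nt * nDatasets
  df <- data.frame(
    gene_id = rep(genes, each = nt * nDatasets),
    age_day = rep(rep(timepoints, times = nDatasets), nGenes),
    dataset_id = rep(rep(sprintf("ds%02d", seq_len(nDatasets)),
                         each = nt), nGenes),
    stringsAsFactors = FALSE)
  mu <- rep(trend, each = nt * nDatasets) * trendSlope *
    (df$age_day - timepoints[1])
  df$value <- 5 + mu + stats::rnorm(rows, 0, noiseSd)
  df <- df[, c("gene_id", "age_day", "value", "dataset_id")]
  list(expr = df,
       truth = data.frame(gene_id = genes, trend = trend,
                          stringsAsFactors = FALSE))
}
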