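# Synthetic spectrum generator. Emulates the structure of the study's
# spectra — singly charged [M+H]+/[M+Na]+ LCO species with B1..B(n-1)
# fragments and, for O-acetylated species, -60 acetic-acid-loss companions
# — degraded by Gaussian m/z jitter, uniform decoy peaks and an optional
# arithmetic polymer-ladder contaminant (a stand-in for the strongly
# UV-absorbing polymeric contaminant seen in early HPLC fractions).
# Intensities are log-normal and are never used in scoring.

#' Simulation configuration
#'
#' Defaults describe the benchmark conditions used throughout: the
#' wild-type species repertoire as ground truth, sodiated ions favoured
#' (as observed), 0.05 Da m/z jitter, 20 uniform decoy peaks over the
#' fragment m/z range, no polymer ladder.
#'
#' @param truth_structures list of [lco_structure()]s (or nomenclature
#'   strings) used as ground truth; default: the distinct wild-type
#'   structures of the reference table.
#' @param adduct_probs named probabilities over `c(H=, Na=)`; must sum to 1.
#' @param mz_jitter_sd Gaussian m/z noise SD in Da (>= 0).
#' @param n_decoys number of uniform decoy peaks per spectrum.
#' @param decoy_mz_range numeric length-2 (low, high) m/z window for decoys.
#' @param polymer_ladder optional `c(start, repeat_da, count)` arithmetic
#'   contaminant ladder.
#' @param intensity_lognormal `c(meanlog, sdlog)` of peak intensities.
#' @param seed integer seed; fully determines the generator output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(truth_structures = NULL,
                       adduct_probs = c(H = 0.3, Na = 0.7),
                       mz_jitter_sd = 0.05,
                       n_decoys = 20L,
                       decoy_mz_range = c(400, 1250),
                       polymer_ladder = NULL,
                       intensity_lognormal = c(5, 1),
                       seed = 42L) {
  if (is.null(truth_structures)) {
    noms <- unique(reference_assignments("wild_type")$structure)
    truth_structures <- lapply(noms, parse_nomenclature)
  }
  truth_structures <- lapply(truth_structures, function(s) {
    if (is.character(s)) parse_nomenclature(s) else s
  })
  stopifnot(all(vapply(truth_structures, inherits, logical(1),
                       "lco_structure")))
  if (!all(sort(names(adduct_probs)) == c("H", "Na")) ||
      abs(sum(adduct_probs) - 1) > 1e-9 || any(adduct_probs < 0)) {
    stop("adduct_probs must be probabilities over H and Na summing to 1",
         call. = FALSE)
  }
  if (mz_jitter_sd < 0) stop("mz_jitter_sd must be >= 0", call. = FALSE)
  if (n_decoys < 0) stop("n_decoys must be >= 0", call. = FALSE)
  if (length(decoy_mz_range) != 2 || decoy_mz_range[1] >= decoy_mz_range[2]) {
    stop("decoy_mz_range must be an increasing (low, high) pair",
         call. = FALSE)
  }
  if (!is.null(polymer_ladder) &&
      (length(polymer_ladder) != 3 || polymer_ladder[2] <= 0 ||
         polymer_ladder[3] < 1)) {
    stop("polymer_ladder must be c(start, repeat_da, count)", call. = FALSE)
  }
  structure(list(truth_structures = truth_structures,
                 adduct_probs = adduct_probs[c("H", "Na")],
                 mz_jitter_sd = mz_jitter_sd,
                 n_decoys = as.integer(n_decoys),
                 decoy_mz_range = as.numeric(decoy_mz_range),
                 polymer_ladder = polymer_ladder,
                 intensity_lognormal = as.numeric(intensity_lognormal),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# core generator; assumes the RNG state is already set by the caller
.generate_peaklist_impl <- function(s, adduct, cfg, sample_id) {
  pset <- predict_spectrum(s, adduct)
  frag <- pset$ions[pset$ions$series == "B" | pset$ions$acetic_acid_loss, ,
                    drop = FALSE]
  mz <- frag$mz_mono + stats::rnorm(nrow(frag), 0, cfg$mz_jitter_sd)
  if (cfg$n_decoys > 0) {
    mz <- c(mz, stats::runif(cfg$n_decoys, cfg$decoy_mz_range[1],
                             cfg$decoy_mz_range[2]))
  }
  if (!is.null(cfg$polymer_ladder)) {
    pl <- cfg$polymer_ladder
    mz <- c(mz, pl[1] + pl[2] * (seq_len(pl[3]) - 1))
  }
  intensity <- stats::rlnorm(length(mz), cfg$intensity_lognormal[1],
                             cfg$intensity_lognormal[2])
  prec_obs <- pset$precursor$mz_mono + stats::rnorm(1, 0, cfg$mz_jitter_sd)
  peaklist(mz, intensity, precursor_mz = prec_obs, sample_id = sample_id,
           metadata = list(truth = format_nomenclature(s),
                           truth_adduct = adduct))
}

#' Generate one synthetic peak list
#'
#' Places each predicted fragment ion (B ions and loss companions) at its
#' monoisotopic m/z plus Gaussian jitter, adds decoys and the optional
#' polymer ladder, draws log-normal intensities and sets the (jittered)
#' precursor m/z. Output is fully determined by `cfg$seed`.
#'
#' @param s an [lco_structure()].
#' @param adduct `"H"` or `"Na"`.
#' @param cfg a [sim_config()].
#' @return A [peaklist()] with the ground truth in its metadata.
#' @export
generate_peaklist <- function(s, adduct = c("H", "Na"), cfg = sim_config()) {
  adduct <- .check_adduct(match.arg(adduct))
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  .generate_peaklist_impl(s, adduct, cfg,
                          sample_id = paste0(format_nomenclature(s),
                                             "/", adduct))
}

#' Generate a paired wild-type / mutant synthetic experiment
#'
#' The wild-type truth is `cfg$truth_structures`; the mutant truth applies
#' [de_O_acetylate()] to every O-acetylated structure (non-acetylated
#' structures are shared, duplicates collapsed). One spectrum is generated
#' per structure with an adduct drawn from `cfg$adduct_probs`.
#'
#' @param cfg a [sim_config()]; its truth must contain at least one
#'   O-acetylated structure.
#' @return A list with `wild_type` and `mutant` (lists of [peaklist()]s)
#'   and `truth`, a data.frame of the per-spectrum ground truth.
#' @export
generate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  noms <- vapply(cfg$truth_structures, format_nomenclature, character(1))
  if (!any(.is_oac(noms))) {
    stop("truth contains no O-acetylated structure", call. = FALSE)
  }
  wt <- cfg$truth_structures[!duplicated(noms)]
  mut_noms <- unique(vapply(wt, function(s) {
    if (s$substituents$o_acetyl) format_nomenclature(de_O_acetylate(s))
    else format_nomenclature(s)
  }, character(1)))
  mut <- lapply(mut_noms, parse_nomenclature)
  set.seed(cfg$seed)
  gen_side <- function(structures, side) {
    lapply(seq_along(structures), function(i) {
      adduct <- sample(c("H", "Na"), 1, prob = cfg$adduct_probs)
      .generate_peaklist_impl(structures[[i]], adduct, cfg,
                              sample_id = sprintf("%s_%02d", side, i))
    })
  }
  wt_pl <- gen_side(wt, "wild_type")
  mut_pl <- gen_side(mut, "mutant")
  truth <- data.frame(
    side = c(rep("wild_type", length(wt_pl)), rep("mutant", length(mut_pl))),
    sample_id = vapply(c(wt_pl, mut_pl), function(p) p$sample_id,
                       character(1)),
    structure = vapply(c(wt_pl, mut_pl), function(p) p$metadata$truth,
                       character(1)),
    adduct = vapply(c(wt_pl, mut_pl), function(p) p$metadata$truth_adduct,
                    character(1)),
    stringsAsFactors = FALSE
  )
  list(wild_type = wt_pl, mutant = mut_pl, truth = truth)
}

#' Fraction of spectra whose true structure is recovered
#'
#' A spectrum counts as recovered when its ground-truth structure string is
#' among the co-ranked top candidates of its annotation result (isobars
#' that the data cannot distinguish therefore still count).
#'
#' @param truth character vector of true nomenclature strings.
#' @param results list of `annotation_result`s, same length.
#' @return Numeric in `[0, 1]`.
#' @export
recovery_rate <- function(truth, results) {
  if (length(truth) != length(results)) {
    stop("truth and results lengths differ", call. = FALSE)
  }
  if (length(truth) == 0) return(NaN)
  hits <- vapply(seq_along(truth), function(i) {
    tc <- top_candidates(results[[i]])
    format_nomenclature(parse_nomenclature(truth[i])) %in% tc$nomenclature
  }, logical(1))
  mean(hits)
}

#' Recovery benchmark over the default search space
#'
#' Draws `n_spectra` (structure, adduct) pairs uniformly from the
#' enumerated search space, generates a noisy spectrum for each, annotates
#' it with the adduct unknown, and reports the [recovery_rate()].
#'
#' @param n_spectra number of spectra (default 200).
#' @param cfg a [sim_config()] providing noise levels and the seed.
#' @param space a [search_space()] to sample from and annotate against.
#' @param params a [match_params()].
#' @return A list with `rate`, `n_spectra` and the per-spectrum `truth`.
#' @export
recovery_benchmark <- function(n_spectra = 200L, cfg = sim_config(),
                               space = search_space(),
                               params = match_params()) {
  structures <- enumerate_structures(space)
  set.seed(cfg$seed)
  idx <- sample.int(length(structures), n_spectra, replace = TRUE)
  adducts <- sample(c("H", "Na"), n_spectra, replace = TRUE,
                    prob = cfg$adduct_probs)
  pls <- lapply(seq_len(n_spectra), function(i) {
    .generate_peaklist_impl(structures[[idx[i]]], adducts[i], cfg,
                            sample_id = sprintf("bench_%03d", i))
  })
  results <- lapply(pls, annotate_spectrum, space = space, params = params)
  truth <- vapply(structures[idx], format_nomenclature, character(1))
  list(rate = recovery_rate(truth, results), n_spectra = n_spectra,
       truth = truth, results = results)
}

#' Annotate a synthetic experiment and run the differential test
#'
#' Annotates every wild-type and mutant spectrum, accepts the co-ranked
#' top candidates of each as that sample's species assignments, and runs
#' [pair_by_acetyl()].
#'
#' @param experiment output of [generate_experiment()].
#' @param space a [search_space()].
#' @param params a [match_params()].
#' @return A `differential_report`.
#' @export
experiment_verdict <- function(experiment, space = search_space(),
                               params = match_params()) {
  accept <- function(pls, id) {
    tops <- lapply(pls, function(pl) {
      top_candidates(annotate_spectrum(pl, space, params))
    })
    df <- do.call(rbind, tops)
    if (is.null(df) || nrow(df) == 0) {
      return(species_set(id, character(0), character(0)))
    }
    species_set(id, df$nomenclature, df$adduct)
  }
  a <- accept(experiment$wild_type, "wild_type")
  b <- accept(experiment$mutant, "mutant")
  pair_by_acetyl(a, b)
}
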