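#' Analysis configuration
#'
#' Bundles every tunable threshold of the circRNA pipeline. Defaults encode
#' the study design this package models: 51-nt reads split into two exact
#' genome matches of at least 20 nt; junctions grouped within +/- 5 nt;
#' candidate filters of >= 100 circular reads for total-RNA libraries and
#' >= 20 reads plus a < 10 kb predicted length for small-RNA libraries;
#' RPKM flooring at 1 and omission below 2 in both samples; a strict 2-fold
#' differential-expression boundary; a knockout/wild-type circular-read
#' ratio below 0.05 calling depletion; and an 8-nt terminal-stem window in
#' which 3 or more consecutive pairings predict circularizability.
#'
#' @param min_segment_len Minimum exact-match length (nt) for each of the two
#'   read segments flanking a circular junction.
#' @param junction_group_tolerance Maximum coordinate difference (nt) on both
#'   junction endpoints for raw junctions to join one cluster.
#' @param min_count_total_rna Minimum circular read count for a candidate from
#'   a total-RNA library.
#' @param min_count_small_rna Minimum circular read count for a candidate from
#'   a small-RNA library.
#' @param max_predicted_len Maximum predicted circRNA length (nt) for small-RNA
#'   library candidates.
#' @param depletion_ratio KO/WT circular-read ratio below which a locus is
#'   called depleted.
#' @param rpkm_floor RPKM values below this are stored as 0.
#' @param rpkm_min_either Records with floored RPKM below this in both samples
#'   are omitted from fold-change classification.
#' @param fold_change_cutoff Strict fold-change boundary for up/down calls.
#' @param stem_window Terminal window length (nt) scanned for stem pairing.
#' @param count_gu_wobble Whether G:U counts as a pairing in stem scoring.
#' @param min_stem_pairs_circular Minimum consecutive terminal pairings for a
#'   circularizable call.
#' @param rng_seed Integer seed used by operations that draw random numbers.
#' @return An object of class `analysis_config` (a validated named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$min_segment_len
#' @export
analysis_config <- function(min_segment_len = 20L,
                            junction_group_tolerance = 5L,
                            min_count_total_rna = 100L,
                            min_count_small_rna = 20L,
                            max_predicted_len = 10000L,
                            depletion_ratio = 0.05,
                            rpkm_floor = 1.0,
                            rpkm_min_either = 2.0,
                            fold_change_cutoff = 2.0,
                            stem_window = 8L,
                            count_gu_wobble = TRUE,
                            min_stem_pairs_circular = 3L,
                            rng_seed = 1L) {
  cfg <- list(
    min_segment_len = as.integer(min_segment_len),
    junction_group_tolerance = as.integer(junction_group_tolerance),
    min_count_total_rna = as.integer(min_count_total_rna),
    min_count_small_rna = as.integer(min_count_small_rna),
    max_predicted_len = as.integer(max_predicted_len),
    depletion_ratio = as.numeric(depletion_ratio),
    rpkm_floor = as.numeric(rpkm_floor),
    rpkm_min_either = as.numeric(rpkm_min_either),
    fold_change_cutoff = as.numeric(fold_change_cutoff),
    stem_window = as.integer(stem_window),
    count_gu_wobble = isTRUE(count_gu_wobble),
    min_stem_pairs_circular = as.integer(min_stem_pairs_circular),
    rng_seed = as.integer(rng_seed)
  )
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  pos <- c("min_segment_len", "junction_group_tolerance", "min_count_total_rna",
           "min_count_small_rna", "max_predicted_len", "stem_window",
           "min_stem_pairs_circular")
  for (f in pos) {
    if (is.na(cfg[[f]]) || cfg[[f]] < (if (f == "junction_group_tolerance") 0L else 1L)) {
      stop(sprintf("config field '%s' must be a positive integer", f), call. = FALSE)
    }
  }
  if (!(cfg$depletion_ratio > 0 && cfg$depletion_ratio < 1)) {
    stop("depletion_ratio must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$rpkm_floor < 0 || cfg$rpkm_min_either < 0 || cfg$fold_change_cutoff <= 0) {
    stop("rpkm_floor/rpkm_min_either must be >= 0 and fold_change_cutoff > 0",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("circsrna analysis configuration\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read or write an analysis configuration as YAML
#'
#' The file holds a flat mapping whose keys are the `analysis_config()`
#' arguments; missing keys take their defaults, unknown keys are an error.
#'
#' @param path File path.
#' @return `read_analysis_config` returns an `analysis_config`;
#'   `write_analysis_config` invisibly returns `path`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param cfg An `analysis_config`.
#' @export
write_analysis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
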