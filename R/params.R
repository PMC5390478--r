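#' Parameters for read-depth and BAF extraction
#'
#' Controls how alignments are binned into read-depth tracks and how
#' heterozygous SNPs are called in the normal sample.
#'
#' @param bin_width Bin width in bp for read-depth tracks.
#' @param min_mapping_quality Reads with mapping quality below this value are
#'   discarded before counting and allele extraction.
#' @param het_min_depth Minimum normal-sample depth at a known SNP site for it
#'   to be eligible as heterozygous.
#' @param het_fraction_window Numeric pair `(low, high)`: a site is called
#'   heterozygous when its minor-allele fraction in the normal sample lies in
#'   the open interval `(low, high)`.
#' @return An object of class `extraction_params`.
#' @export
extraction_params <- function(bin_width = 2000L, min_mapping_quality = 10L,
                              het_min_depth = 8L,
                              het_fraction_window = c(0.3, 0.7)) {
  stopifnot(bin_width > 0, min_mapping_quality >= 0, het_min_depth >= 1,
            length(het_fraction_window) == 2,
            het_fraction_window[1] >= 0, het_fraction_window[2] <= 1,
            het_fraction_window[1] < het_fraction_window[2])
  structure(list(bin_width = as.integer(bin_width),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 het_min_depth = as.integer(het_min_depth),
                 het_fraction_window = as.numeric(het_fraction_window)),
            class = "extraction_params")
}

#' Parameters for double sliding-window segmentation
#'
#' @param initial_window First-pass window size, in bins (>= 2).
#' @param tau_logr First-pass threshold on the absolute difference of
#'   adjacent-window mean log2 ratios.
#' @param tau_baf First-pass threshold on the absolute difference of
#'   adjacent-window mean cBAF values.
#' @param tau_merge_logr Merge threshold on adjacent-segment mean log2 ratios;
#'   also terminates the multi-scale loop.
#' @param tau_merge_baf Merge threshold on adjacent-segment mean cBAF.
#' @param baf_mode If `FALSE`, segmentation uses the log-ratio signal only
#'   (no BAF term in the score, no BAF condition when merging) and cnLOH
#'   cannot be called downstream.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(initial_window = 10L, tau_logr = 0.4,
                                tau_baf = 0.15, tau_merge_logr = 0.1,
                                tau_merge_baf = 0.05, baf_mode = TRUE) {
  stopifnot(initial_window >= 2, tau_logr > 0, tau_baf > 0,
            tau_merge_logr > 0, tau_merge_baf > 0,
            tau_merge_logr < tau_logr, tau_merge_baf < tau_baf)
  structure(list(initial_window = as.integer(initial_window),
                 tau_logr = tau_logr, tau_baf = tau_baf,
                 tau_merge_logr = tau_merge_logr,
                 tau_merge_baf = tau_merge_baf,
                 baf_mode = isTRUE(baf_mode)),
            class = "segmentation_params")
}

#' Parameters for copy-neutral LOH calling
#'
#' A segment is flagged cnLOH when `|mean_logr| < tau_logr` (copy-neutral)
#' and `0.5 - mean_cbaf < tau_baf` (near-complete allelic imbalance), and it
#' passes the size filters.
#'
#' @param tau_logr Threshold on the absolute segment mean log2 ratio.
#' @param tau_baf Threshold on the distance of the segment mean cBAF from 0.5.
#' @param min_segment_length Minimum segment length in bp (0 disables).
#' @param min_snps Minimum number of SNPs supporting the segment (0 disables).
#' @return An object of class `cnloh_params`.
#' @export
cnloh_params <- function(tau_logr = 0.1, tau_baf = 0.1,
                         min_segment_length = 1e6, min_snps = 20L) {
  stopifnot(tau_logr > 0, tau_baf > 0, min_segment_length >= 0, min_snps >= 0)
  structure(list(tau_logr = tau_logr, tau_baf = tau_baf,
                 min_segment_length = as.numeric(min_segment_length),
                 min_snps = as.integer(min_snps)),
            class = "cnloh_params")
}

#' Chromosome lengths of a generic human-scale autosome set
#'
#' Convenience default genome for the simulator: 22 autosome lengths on the
#' scale of the human reference (rounded to 1 Mbp).
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
default_genome <- function() {
  lens <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
            115, 107, 102, 90, 81, 78, 59, 63, 48, 51) * 1e6
  names(lens) <- paste0("chr", seq_along(lens))
  lens
}

#' Parameters for the tumor/normal simulator
#'
#' @param genome Named vector of chromosome lengths in bp.
#' @param bin_width Bin width in bp for the simulated depth tracks.
#' @param contamination Normal-cell contamination fraction `c` in `[0, 1)`.
#' @param n_events Number of somatic events to place on the genome.
#' @param event_size_range Length-2 vector: event sizes are drawn log-uniform
#'   between these bounds (bp).
#' @param event_types Character vector of event types to draw from, uniformly;
#'   subset of `"deletion"`, `"amplification"`, `"cnloh"`.
#' @param min_event_gap Minimum distance in bp between placed events, and
#'   from events to chromosome ends (default 0: only overlap is forbidden).
#'   Setting it to at least twice the segmentation window guarantees every
#'   copy-number piece is long enough for the double window to resolve.
#' @param snp_spacing Mean spacing of heterozygous SNPs in bp (exponential
#'   inter-arrival distances, i.e. a homogeneous Poisson point process).
#' @param mean_depth Mean read depth per bin used when a synthetic normal
#'   track has to be generated (no real normal track supplied).
#' @param median_filter_width Width in bins of the median filter that turns
#'   the sampled depth chain into the noise-free baseline.
#' @param depth_noise `"poisson"` (default) adds independent Poisson noise to
#'   the baseline for both samples; `"none"` emits the rounded noise-free
#'   expected depths (useful for exact-recovery checks).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(genome = default_genome(), bin_width = 2000L,
                              contamination = 0, n_events = 20L,
                              event_size_range = c(1e6, 30e6),
                              event_types = c("deletion", "amplification",
                                              "cnloh"),
                              min_event_gap = 0,
                              snp_spacing = 1500, mean_depth = 100,
                              median_filter_width = 9L,
                              depth_noise = c("poisson", "none")) {
  depth_noise <- match.arg(depth_noise)
  stopifnot(length(genome) >= 1, !is.null(names(genome)), all(genome > 0),
            bin_width > 0, contamination >= 0, contamination < 1,
            n_events >= 0, length(event_size_range) == 2,
            event_size_range[1] > 0,
            event_size_range[1] <= event_size_range[2],
            all(event_types %in% c("deletion", "amplification", "cnloh")),
            min_event_gap >= 0,
            snp_spacing > 0, mean_depth > 0, median_filter_width >= 1,
            median_filter_width %% 2 == 1)
  structure(list(genome = genome, bin_width = as.integer(bin_width),
                 contamination = contamination,
                 n_events = as.integer(n_events),
                 event_size_range = as.numeric(event_size_range),
                 event_types = event_types,
                 min_event_gap = as.numeric(min_event_gap),
                 snp_spacing = snp_spacing, mean_depth = mean_depth,
                 median_filter_width = as.integer(median_filter_width),
                 depth_noise = depth_noise),
            class = "simulation_params")
}
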