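#' Integration-site preference model
#'
#' A two-component mixture: with probability `pi_tss` a site falls uniformly
#' within `window_bp` of a uniformly chosen TSS; otherwise it falls uniformly
#' anywhere on the genome. `pi_tss` is the single knob that distinguishes a
#' gammaretroviral-like cohort (strong TSS preference) from a foamy-virus-like
#' cohort (weak preference).
#'
#' @param pi_tss Probability of drawing from the TSS-proximal component,
#'   in `[0, 1]`.
#' @param window_bp Half-width of the TSS-proximal component in bp (> 0).
#' @param label Cohort name, e.g. `"FV"` or `"RV"`.
#' @return An object of class `IntegrationModel`.
#' @export
integration_model <- function(pi_tss, window_bp = 15000L, label = "cohort") {
  if (!(pi_tss >= 0 && pi_tss <= 1))
    stop("`pi_tss` must lie in [0, 1]", call. = FALSE)
  if (!(window_bp > 0)) stop("`window_bp` must be positive", call. = FALSE)
  structure(list(pi_tss = pi_tss, window_bp = as.integer(window_bp),
                 label = as.character(label)),
            class = "IntegrationModel")
}

#' @export
print.IntegrationModel <- function(x, ...) {
  cat("IntegrationModel '", x$label, "': pi_tss = ", x$pi_tss,
      ", window = ", x$window_bp, " bp\n", sep = "")
  invisible(x)
}

#' Exact genome fraction covered by TSS windows
#'
#' Computes, by interval union, the fraction of genome positions lying within
#' `window` bp of at least one TSS. Under a genome-uniform integration model
#' this is the expected within-window fraction; the mixture expectation is
#' `pi_tss + (1 - pi_tss) * c`.
#'
#' @param genome Reference genome.
#' @param ann A `GenomeAnnotation`.
#' @param window Window half-width in bp (default 15000).
#' @return A single fraction in `[0, 1]`.
#' @export
tss_window_coverage <- function(genome, ann, window = 15000L) {
  gchr <- .as_genome_chr(genome)
  lens <- nchar(gchr)
  genes <- ann$genes
  if (nrow(genes) == 0) return(0)
  tss <- tss_positions(genes)
  covered <- 0
  for (chrom in unique(genes$chrom)) {
    idx <- genes$chrom == chrom
    L <- lens[[chrom]]
    ir <- IRanges::IRanges(start = pmax(1L, tss[idx] + 1L - window),
                           end = pmin(L, tss[idx] + 1L + window))
    covered <- covered + sum(IRanges::width(IRanges::reduce(ir)))
  }
  covered / sum(lens)
}

#' Simulate an integration-site cohort
#'
#' Each site is drawn independently under an [integration_model()]: with
#' probability `pi_tss`, uniformly within `window_bp` of a uniformly chosen
#' TSS (clipped to the chromosome); otherwise uniformly over the genome.
#' Orientation is uniform. Sites colliding at an identical position are
#' redrawn so the cohort consists of distinct ("independent") loci.
#'
#' @param genome Reference genome.
#' @param ann A `GenomeAnnotation`; must contain at least one gene when
#'   `pi_tss > 0`.
#' @param n Number of sites.
#' @param model An `IntegrationModel`.
#' @param seed Integer seed.
#' @param protocol Optional [lmpcr_protocol()]. When supplied, sites whose
#'   junction fragment would be lost under the protocol (PstI-first
#'   cleavage, flank too short/long, no restriction site) are redrawn, so the
#'   cohort consists entirely of LM-PCR-recoverable sites — mirroring the
#'   fact that an observed cohort contains only recoverable loci.
#' @return A data.frame with columns `chrom`, `pos` (0-based), `orient`
#'   (`+`/`-`), `cohort`.
#' @export
simulate_integrations <- function(genome, ann, n, model, seed,
                                  protocol = NULL) {
  gchr <- .as_genome_chr(genome)
  lens <- nchar(gchr)
  stopifnot(inherits(model, "IntegrationModel"), n >= 0)
  if (model$pi_tss > 0 && nrow(ann$genes) == 0)
    stop("annotation must contain at least one gene when pi_tss > 0",
         call. = FALSE)
  if (n > sum(lens))
    stop("cannot draw ", n, " distinct sites from ", sum(lens),
         " genome positions", call. = FALSE)
  genes <- ann$genes
  tss <- tss_positions(genes)
  w <- model$window_bp

  .with_seed(seed, {
    chrom <- character(0); pos <- integer(0); orient <- character(0)
    keys <- character(0)
    guard <- 0L
    while (length(pos) < n) {
      guard <- guard + 1L
      if (guard > 200L)
        stop("failed to accumulate ", n, " distinct recoverable sites; ",
             "the genome/protocol constraints are too tight", call. = FALSE)
      m <- max(16L, ceiling(1.5 * (n - length(pos))))
      from_tss <- stats::runif(m) < model$pi_tss
      c_new <- character(m); p_new <- integer(m)
      n_bg <- sum(!from_tss)
      if (n_bg > 0) {
        bg_chrom <- sample(names(gchr), n_bg, replace = TRUE, prob = lens)
        bg_pos <- as.integer(floor(stats::runif(n_bg) * lens[bg_chrom]))
        c_new[!from_tss] <- bg_chrom; p_new[!from_tss] <- bg_pos
      }
      n_ts <- sum(from_tss)
      if (n_ts > 0) {
        gi <- sample.int(nrow(genes), n_ts, replace = TRUE)
        off <- sample.int(2L * w + 1L, n_ts, replace = TRUE) - w - 1L
        ch <- genes$chrom[gi]
        p <- pmin(pmax(tss[gi] + off, 0L), lens[ch] - 1L)
        c_new[from_tss] <- ch; p_new[from_tss] <- p
      }
      o_new <- sample(c("+", "-"), m, replace = TRUE)
      k_new <- paste0(c_new, ":", p_new)
      keep <- which(!duplicated(k_new) & !(k_new %in% keys))
      for (i in keep) {
        if (length(pos) >= n) break
        if (!is.null(protocol)) {
          frag <- .digest_flank(gchr[[c_new[i]]], p_new[i], o_new[i], protocol)
          if (frag$status != "ok") next
        }
        chrom <- c(chrom, c_new[i]); pos <- c(pos, p_new[i])
        orient <- c(orient, o_new[i]); keys <- c(keys, k_new[i])
      }
    }
    data.frame(chrom = chrom, pos = pos, orient = orient,
               cohort = model$label, stringsAsFactors = FALSE)
  })
}
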