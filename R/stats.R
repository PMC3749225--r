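# Site classification relative to the gene model, TSS-centred density
# profiles, and 2x2 cohort comparisons.

#' Signed distance to the nearest transcription start site
#'
#' For each site, minimises `|pos - TSS|` over genes on the site's
#' chromosome; ties are broken by the lexicographically smaller gene id.
#' The sign is strand-aware: positive means downstream of the TSS in the
#' gene's orientation (`pos - TSS` for `+` strand genes, `TSS - pos` for
#' `-` strand genes), negative means upstream.
#'
#' @param sites Data.frame with `chrom` and `pos` (0-based) columns.
#' @param ann A `GenomeAnnotation`.
#' @return A data.frame with `nearest_tss_gene` and `tss_distance`, both
#'   `NA` for sites on chromosomes carrying no annotated gene.
#' @export
distance_to_nearest_tss <- function(sites, ann) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  genes <- ann$genes
  n <- nrow(sites)
  gene_out <- rep(NA_character_, n)
  dist_out <- rep(NA_integer_, n)
  if (n == 0 || nrow(genes) == 0)
    return(data.frame(nearest_tss_gene = gene_out, tss_distance = dist_out,
                      stringsAsFactors = FALSE))
  tss_all <- tss_positions(genes)
  for (chrom in unique(sites$chrom)) {
    si <- which(sites$chrom == chrom)
    gi <- which(genes$chrom == chrom)
    if (!length(gi)) next
    ord <- order(tss_all[gi], genes$gene_id[gi])
    gi <- gi[ord]
    tss <- tss_all[gi]
    pos <- sites$pos[si]
    left <- findInterval(pos, tss)           # index of last tss <= pos
    right <- pmin(left + 1L, length(tss))
    left <- pmax(left, 1L)
    dl <- abs(pos - tss[left])
    dr <- abs(pos - tss[right])
    # choose the closer TSS; on an exact |distance| tie take the smaller id
    use_left <- dl < dr |
      (dl == dr & genes$gene_id[gi[left]] <= genes$gene_id[gi[right]])
    pick <- ifelse(use_left, gi[left], gi[right])
    signed <- ifelse(genes$strand[pick] == "+",
                     pos - tss_all[pick], tss_all[pick] - pos)
    gene_out[si] <- genes$gene_id[pick]
    dist_out[si] <- as.integer(signed)
  }
  data.frame(nearest_tss_gene = gene_out, tss_distance = dist_out,
             stringsAsFactors = FALSE)
}

#' Classify integration sites relative to the gene model
#'
#' Adds, per site: whether it falls inside a transcriptional unit
#' (`tx_start <= pos < tx_end`), the nearest TSS and its signed distance,
#' whether it lies within `tss_window` bp of a TSS (boundary inclusive,
#' symmetric), and — for every label set of the annotation — whether it lies
#' inside or within `label_window` bp of a gene carrying the label.
#'
#' @param sites Data.frame with `chrom`, `pos` (and optionally `orient`).
#' @param ann A `GenomeAnnotation`.
#' @param tss_window TSS-proximity window half-width in bp (default 15000).
#' @param label_window Labelled-gene proximity threshold in bp
#'   (default 30000), inclusive.
#' @param label_anchor `"interval"` (default): distance is measured to the
#'   gene interval `[tx_start, tx_end)`, 0 inside, so inside-gene hits count.
#'   `"tss"`: distance to the labelled gene's TSS instead.
#' @return The input data.frame with columns `in_gene`, `nearest_tss_gene`,
#'   `tss_distance`, `within_tss_window`, and one `within_<label>` column
#'   per label set.
#' @export
classify_sites <- function(sites, ann, tss_window = 15000L,
                           label_window = 30000L,
                           label_anchor = c("interval", "tss")) {
  label_anchor <- match.arg(label_anchor)
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  genes <- ann$genes
  n <- nrow(sites)
  nd <- distance_to_nearest_tss(sites, ann)
  res <- cbind(sites,
               in_gene = rep(FALSE, n),
               nd,
               within_tss_window = !is.na(nd$tss_distance) &
                 abs(nd$tss_distance) <= tss_window)
  tss_all <- tss_positions(genes)
  for (chrom in unique(sites$chrom)) {
    si <- which(sites$chrom == chrom)
    gi <- which(genes$chrom == chrom)
    if (!length(gi)) next
    for (j in si) {
      p <- sites$pos[j]
      res$in_gene[j] <- any(genes$tx_start[gi] <= p & p < genes$tx_end[gi])
    }
  }
  for (lab in names(ann$label_sets)) {
    col <- paste0("within_", lab)
    res[[col]] <- rep(FALSE, n)
    lab_gi <- which(genes$gene_id %in% ann$label_sets[[lab]])
    if (!length(lab_gi)) next
    for (chrom in unique(sites$chrom)) {
      si <- which(sites$chrom == chrom)
      gi <- lab_gi[genes$chrom[lab_gi] == chrom]
      if (!length(gi)) next
      for (j in si) {
        p <- sites$pos[j]
        d <- if (label_anchor == "interval")
          pmax(genes$tx_start[gi] - p, p - (genes$tx_end[gi] - 1L), 0L)
        else
          abs(p - tss_all[gi])
        res[[col]][j] <- any(d <= label_window)
      }
    }
  }
  res
}

#' TSS-centred integration density profile
#'
#' Bins each site's signed nearest-TSS distance over a window centred on the
#' TSS and expresses each bin as percent of all integrations per kb:
#' `percent_per_kb = (count / total_sites * 100) / width_kb`. Sites beyond
#' the window are excluded from the bins but kept in `total_sites`; sites
#' with no defined TSS distance (no gene on their chromosome) are excluded
#' entirely and counted in `n_unassigned`.
#'
#' @param sites Data.frame with `chrom`, `pos`.
#' @param ann A `GenomeAnnotation`.
#' @param window Window half-width in bp (default 50000, i.e. a 100-kb
#'   window centred on the TSS).
#' @param bin_edges Strictly increasing signed edges spanning exactly
#'   `[-window, window]`. Default `c(-50, -25, -10, -5, -1, 0, 1, 5, 10,
#'   25, 50) * 1000`. Bins are left-open/right-closed with the lowest edge
#'   included.
#' @return An object of class `density_profile`: a list with `bins` (a
#'   data.frame `bin_start`, `bin_end`, `count`, `percent_per_kb`),
#'   `total_sites` and `n_unassigned`.
#' @export
tss_density_profile <- function(sites, ann, window = 50000L,
                                bin_edges = NULL) {
  if (is.null(bin_edges))
    bin_edges <- c(-50, -25, -10, -5, -1, 0, 1, 5, 10, 25, 50) * 1000
  bin_edges <- as.numeric(bin_edges)
  if (any(diff(bin_edges) <= 0))
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  if (bin_edges[1] != -window || bin_edges[length(bin_edges)] != window)
    stop("`bin_edges` must span exactly [-window, +window]", call. = FALSE)
  d <- distance_to_nearest_tss(sites, ann)$tss_distance
  n_unassigned <- sum(is.na(d))
  d <- d[!is.na(d)]
  total <- length(d)
  idx <- findInterval(d, bin_edges, left.open = TRUE)
  idx[d == bin_edges[1]] <- 1L
  m <- length(bin_edges) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= m], nbins = m)
  width_kb <- diff(bin_edges) / 1000
  ppk <- if (total > 0) (counts / total * 100) / width_kb else
    rep(0, m)
  structure(list(
    bins = data.frame(bin_start = bin_edges[-length(bin_edges)],
                      bin_end = bin_edges[-1],
                      count = counts,
                      percent_per_kb = ppk),
    total_sites = total,
    n_unassigned = n_unassigned), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("TSS-centred density profile:", x$total_sites, "sites (",
      sum(x$bins$count), "in window,", x$n_unassigned, "unassigned )\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Write a density profile as TSV
#'
#' @param profile A `density_profile`.
#' @param path File path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare two cohort proportions with a 2x2 test
#'
#' Builds the table `[[k_a, n_a - k_a], [k_b, n_b - k_b]]` and tests equality
#' of proportions. `pearson` computes the 1-df chi-square statistic
#' `n (ad - bc)^2 / (r1 r2 c1 c2)`; `yates` applies the continuity
#' correction (`|ad - bc|` reduced by `n/2`, floored at 0); `fisher`
#' computes the exact two-sided hypergeometric p-value. A degenerate table
#' (any zero margin) carries no information about association and returns
#' statistic 0, p = 1.
#'
#' @param k_a,n_a Successes and total for cohort A (`0 <= k_a <= n_a`,
#'   `n_a > 0`).
#' @param k_b,n_b Successes and total for cohort B.
#' @param method `"pearson"` (default), `"yates"` or `"fisher"`.
#' @return An object of class `contingency_result`: list with `table`
#'   (2x2 integer matrix), `method`, `statistic` (`NA` for fisher), `df`
#'   (1) and `p_value`. A warning recommends `fisher` when any expected
#'   cell count falls below 1 under a chi-square method.
#' @examples
#' compare_categories(13, 100, 25, 100)           # FV vs RV within 15 kb
#' compare_categories(13, 100, 25, 100, method = "yates")
#' @export
compare_categories <- function(k_a, n_a, k_b, n_b,
                               method = c("pearson", "yates", "fisher")) {
  method <- match.arg(method)
  stopifnot(n_a > 0, n_b > 0, k_a >= 0, k_b >= 0, k_a <= n_a, k_b <= n_b)
  tab <- matrix(as.integer(c(k_a, n_a - k_a, k_b, n_b - k_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(cohort = c("A", "B"),
                                outcome = c("yes", "no")))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  degenerate <- any(c(r1, r2, c1, c2) == 0)

  if (method == "fisher") {
    statistic <- NA_real_
    p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  } else {
    if (!degenerate) {
      expected <- outer(c(r1, r2), c(c1, c2)) / n
      if (min(expected) < 1)
        warning("expected cell count below 1; consider method = 'fisher'",
                call. = FALSE)
      delta <- abs(as.numeric(a) * d - as.numeric(b) * c_)
      if (method == "yates") delta <- max(delta - n / 2, 0)
      statistic <- n * delta^2 / (as.numeric(r1) * r2 * c1 * c2)
    } else {
      statistic <- 0
    }
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  structure(list(table = tab, method = method, statistic = statistic,
                 df = 1L, p_value = p),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 comparison (", x$method, "):\n", sep = "")
  print(x$table)
  if (!is.na(x$statistic))
    cat("X-squared =", format(x$statistic, digits = 5), ", df =", x$df,
        ", ")
  cat("p-value =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
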