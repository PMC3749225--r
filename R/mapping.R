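# Desk-scale flank mapper: substitution-only, both strands, unique best
# placement. Seed-and-extend by pigeonhole: a placement with at most k
# substitutions must match at least one of k+1 disjoint seeds exactly, so
# exact seed hits (C-level fixed-string search) enumerate every candidate
# placement, which is then verified by direct mismatch counting. Equivalent
# to an exhaustive every-offset scan of both strands.

# All exact occurrences (1-based starts) of `pat` in `subject`.
.find_fixed <- function(pat, subject) {
  m <- gregexpr(pat, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Candidate placements (1-based starts) of `query` in one chromosome with
# <= k mismatches, by pigeonhole seeding.
.seed_candidates <- function(query, chrom_seq, k) {
  L <- nchar(query)
  n_seed <- k + 1L
  seed_len <- L %/% n_seed
  starts <- (seq_len(n_seed) - 1L) * seed_len + 1L
  cand <- integer(0)
  for (f in starts) {
    seed <- substr(query, f, f + seed_len - 1L)
    hits <- .find_fixed(seed, chrom_seq)
    cand <- c(cand, hits - f + 1L)
  }
  cand <- unique(cand)
  cand[cand >= 1L & cand + L - 1L <= nchar(chrom_seq)]
}

#' Map genomic flanks onto the reference
#'
#' Places each flank on either strand of the reference allowing up to
#' `max_mismatches` substitutions (no indels). A flank is `mapped` only if a
#' single best-scoring placement exists and any runner-up placement (within
#' the mismatch budget) has at least `uniqueness_margin` more mismatches;
#' multiple equally good or insufficiently separated placements give
#' `ambiguous`, and no placement at all gives `unmapped`.
#'
#' The reported `pos` is the 0-based position of the flank's first base in
#' junction orientation — the genomic base adjacent to the LTR — so that a
#' mapped read reproduces the simulator's `IntegrationSite` coordinate
#' exactly: for a `+` placement starting at `s`, `pos = s`; for a `-`
#' placement (the reverse complement of the flank matches the `+` strand at
#' `[s, s + L - 1]`), `pos = s + L - 1`.
#'
#' @param flank A single flank sequence (A/C/G/T only).
#' @param flanks Character vector of flanks, or a data.frame with `read_id`
#'   and `flank_seq` columns (e.g. `ok` rows of [parse_junction_reads()]).
#' @param genome Reference genome.
#' @param max_mismatches Mismatch budget per placement (default 2).
#' @param uniqueness_margin Required mismatch separation between best and
#'   runner-up placements (default 2).
#' @return A data.frame with one row per flank: `read_id`, `status`
#'   (`mapped`/`unmapped`/`ambiguous`), `chrom`, `pos`, `orient`,
#'   `mismatches` (placement columns `NA` unless mapped).
#' @export
map_flanks <- function(flanks, genome, max_mismatches = 2L,
                       uniqueness_margin = 2L) {
  if (is.data.frame(flanks)) {
    ids <- flanks$read_id
    seqs <- flanks$flank_seq
  } else {
    seqs <- as.character(flanks)
    ids <- if (!is.null(names(seqs))) names(seqs) else
      sprintf("flank%05d", seq_along(seqs))
  }
  stopifnot(max_mismatches >= 0, uniqueness_margin >= 0)
  bad <- !.is_dna(seqs)
  if (any(bad))
    stop("flank(s) ", paste(ids[bad], collapse = ", "),
         " contain characters outside {A,C,G,T}", call. = FALSE)

  gchr <- .as_genome_chr(genome)
  graw <- lapply(gchr, charToRaw)
  k <- as.integer(max_mismatches)

  n <- length(seqs)
  status <- character(n)
  chrom <- rep(NA_character_, n); pos <- rep(NA_integer_, n)
  orient <- rep(NA_character_, n); mism <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    q_fwd <- seqs[i]
    L <- nchar(q_fwd)
    if (L < k + 1L)
      stop("flank ", ids[i], " is shorter than max_mismatches + 1", call. = FALSE)
    queries <- c("+" = q_fwd, "-" = .revcomp(q_fwd))
    hit_chrom <- character(0); hit_strand <- character(0)
    hit_start <- integer(0); hit_mm <- integer(0)
    for (strand in c("+", "-")) {
      q <- queries[[strand]]
      qraw <- charToRaw(q)
      for (ch in names(gchr)) {
        for (s in .seed_candidates(q, gchr[[ch]], k)) {
          mm <- sum(graw[[ch]][s:(s + L - 1L)] != qraw)
          if (mm <= k) {
            hit_chrom <- c(hit_chrom, ch)
            hit_strand <- c(hit_strand, strand)
            hit_start <- c(hit_start, s)
            hit_mm <- c(hit_mm, mm)
          }
        }
      }
    }
    if (!length(hit_mm)) { status[i] <- "unmapped"; next }
    best <- min(hit_mm)
    n_best <- sum(hit_mm == best)
    runner <- if (length(hit_mm) > 1L) sort(hit_mm)[2L] else Inf
    if (n_best > 1L || runner - best < uniqueness_margin) {
      status[i] <- "ambiguous"; next
    }
    b <- which.min(hit_mm)
    status[i] <- "mapped"
    chrom[i] <- hit_chrom[b]
    orient[i] <- hit_strand[b]
    pos[i] <- if (hit_strand[b] == "+") hit_start[b] - 1L else
      hit_start[b] - 1L + L - 1L
    mism[i] <- hit_mm[b]
  }
  data.frame(read_id = ids, status = status, chrom = chrom, pos = pos,
             orient = orient, mismatches = mism, stringsAsFactors = FALSE)
}

#' @rdname map_flanks
#' @export
map_flank <- function(flank, genome, max_mismatches = 2L,
                      uniqueness_margin = 2L) {
  stopifnot(length(flank) == 1L)
  map_flanks(flank, genome, max_mismatches, uniqueness_margin)
}

#' Export mapped sites as BED6
#'
#' One line per mapped read: chrom, pos, pos + 1, read_id, mismatches,
#' orient (0-based half-open single-base interval at the junction base).
#'
#' @param mapping Output of [map_flanks()].
#' @param path File path.
#' @export
write_mapping_bed <- function(mapping, path) {
  m <- mapping[mapping$status == "mapped", , drop = FALSE]
  out <- data.frame(m$chrom, m$pos, m$pos + 1L, m$read_id, m$mismatches,
                    m$orient)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
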