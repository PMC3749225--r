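# LM-PCR junction-library simulation: MseI/PstI digest, linker ligation,
# nested PCR between an LTR primer and a linker primer.

.LMPCR_SEQS <- list(
  linker_top = "GTAATACGACTCACTATAGGGCTCCGCTTAAGGGACGAGGCGAATTCCCTGAT",
  linker_primer_outer = "GTAATACGACTCACTATAGGGC",
  linker_primer_nested = "AGGGCTCCGCTTAAGGGAC",
  FV = list(ltr_primer_outer = "GTCTATGAGGAGCAGGAGTA",
            ltr_primer_nested = "CCTCCTTCCCTGTAATACTC"),
  RV = list(ltr_primer_outer = "TAACCAATCAGTTCGCTTCTCGCTT",
            ltr_primer_nested = "CTCAATAAAAGAGCCCACAACCCC")
)

#' LM-PCR protocol definition
#'
#' Bundles the restriction enzymes, linker, primers and recovery thresholds
#' of a ligation-mediated PCR junction protocol. Defaults are the literal
#' reagents of the FV/RV integration-site assay: an MseI + PstI double
#' digest, an MseI-compatible linker, and vector-specific nested LTR primers.
#'
#' Enzyme semantics: MseI recognises `TTAA` and cuts after 1 base (`T^TAA`);
#' PstI recognises `CTGCAG` and cuts after 5 bases (`CTGCA^G`). An enzyme's
#' `action` is `"ligate"` (its cut defines the fragment end that receives the
#' linker — MseI) or `"discard"` (a fragment whose first restriction site
#' belongs to this enzyme is lost before linker ligation — PstI, whose
#' accepted role is suppressing internal-vector amplicons).
#'
#' @param vector `"FV"` or `"RV"`; selects the LTR primer pair.
#' @param enzymes Named list; each element a list with `site` (recognition
#'   sequence), `cut` (bases consumed before the cut) and `action`.
#' @param pstI_loss If `FALSE`, `"discard"` enzymes are ignored (no
#'   co-digestion loss).
#' @param min_flank_bp Minimum recoverable genomic flank length (default 20).
#' @param max_fragment_bp Maximum amplifiable flank length (default 600, a
#'   typical LM-PCR amplicon ceiling). May be `Inf`.
#' @param per_base_error Per-base substitution error probability applied to
#'   simulated reads (default 0.001, a Sanger-scale rate).
#' @param duplicates Number of reads emitted per recovered fragment
#'   (default 1).
#' @param linker_top,linker_primer_outer,linker_primer_nested,ltr_primer_outer,ltr_primer_nested
#'   Override individual sequences; defaults follow `vector`.
#' @return An object of class `LmPcrProtocol`.
#' @export
lmpcr_protocol <- function(vector = c("FV", "RV"),
                           enzymes = list(
                             MseI = list(site = "TTAA", cut = 1L,
                                         action = "ligate"),
                             PstI = list(site = "CTGCAG", cut = 5L,
                                         action = "discard")),
                           pstI_loss = TRUE,
                           min_flank_bp = 20L,
                           max_fragment_bp = 600L,
                           per_base_error = 0.001,
                           duplicates = 1L,
                           linker_top = .LMPCR_SEQS$linker_top,
                           linker_primer_outer = .LMPCR_SEQS$linker_primer_outer,
                           linker_primer_nested = .LMPCR_SEQS$linker_primer_nested,
                           ltr_primer_outer = NULL,
                           ltr_primer_nested = NULL) {
  vector <- match.arg(vector)
  if (is.null(ltr_primer_outer))
    ltr_primer_outer <- .LMPCR_SEQS[[vector]]$ltr_primer_outer
  if (is.null(ltr_primer_nested))
    ltr_primer_nested <- .LMPCR_SEQS[[vector]]$ltr_primer_nested
  seqs <- c(linker_top = linker_top,
            linker_primer_outer = linker_primer_outer,
            linker_primer_nested = linker_primer_nested,
            ltr_primer_outer = ltr_primer_outer,
            ltr_primer_nested = ltr_primer_nested)
  bad <- !.is_dna(seqs)
  if (any(bad))
    stop("primer/linker sequence(s) ", paste(names(seqs)[bad], collapse = ", "),
         " must be non-empty and restricted to {A,C,G,T}", call. = FALSE)
  for (e in names(enzymes)) {
    en <- enzymes[[e]]
    stopifnot(.is_dna(en$site), en$cut >= 0, en$cut <= nchar(en$site),
              en$action %in% c("ligate", "discard"))
  }
  stopifnot(min_flank_bp >= 1, max_fragment_bp >= min_flank_bp,
            per_base_error >= 0, per_base_error < 1, duplicates >= 1)
  structure(list(vector = vector, enzymes = enzymes, pstI_loss = pstI_loss,
                 min_flank_bp = as.integer(min_flank_bp),
                 max_fragment_bp = max_fragment_bp,
                 per_base_error = per_base_error,
                 duplicates = as.integer(duplicates),
                 linker_top = linker_top,
                 linker_primer_outer = linker_primer_outer,
                 linker_primer_nested = linker_primer_nested,
                 ltr_primer_outer = ltr_primer_outer,
                 ltr_primer_nested = ltr_primer_nested),
            class = "LmPcrProtocol")
}

#' @export
print.LmPcrProtocol <- function(x, ...) {
  cat("LmPcrProtocol (", x$vector, " LTR primers): enzymes ",
      paste(names(x$enzymes), collapse = "+"),
      ", flank ", x$min_flank_bp, "-", x$max_fragment_bp,
      " bp, per-base error ", x$per_base_error, "\n", sep = "")
  invisible(x)
}

# Simulate the restriction digest of one junction fragment.
#
# The flank starts at `pos` (0-based, the genomic base flanking the LTR end)
# and runs in the `orient` direction: rightwards on the + strand for "+",
# leftwards (reverse-complemented) for "-". The flank sequence is scanned
# for the first restriction site of any active enzyme; a "discard" enzyme
# first means the fragment is lost, a "ligate" enzyme truncates the flank at
# its cut point. Returns list(status, flank) with status one of ok,
# pstI_cleaved, flank_too_short, fragment_too_long, no_enzyme_site.
.digest_flank <- function(chrom_seq, pos, orient, protocol) {
  L <- nchar(chrom_seq)
  enz <- protocol$enzymes
  if (!protocol$pstI_loss)
    enz <- Filter(function(e) e$action != "discard", enz)
  if (!length(Filter(function(e) e$action == "ligate", enz)))
    stop("protocol needs at least one 'ligate' enzyme", call. = FALSE)
  max_site <- max(vapply(enz, function(e) nchar(e$site), integer(1)))
  scan <- if (is.finite(protocol$max_fragment_bp))
    protocol$max_fragment_bp + max_site else L

  if (orient == "+") {
    end1 <- min(L, pos + scan)          # 1-based inclusive end of the window
    window <- substr(chrom_seq, pos + 1L, end1)
    truncated <- end1 < L
  } else {
    start1 <- max(1L, pos + 2L - scan)
    window <- .revcomp(substr(chrom_seq, start1, pos + 1L))
    truncated <- start1 > 1L
  }

  first_at <- Inf; first_enz <- NULL
  for (e in names(enz)) {
    hit <- regexpr(enz[[e]]$site, window, fixed = TRUE)
    if (hit > 0 && hit < first_at) { first_at <- hit; first_enz <- e }
  }
  if (is.null(first_enz)) {
    status <- if (truncated) "fragment_too_long" else "no_enzyme_site"
    return(list(status = status, flank = NA_character_))
  }
  if (enz[[first_enz]]$action == "discard")
    return(list(status = "pstI_cleaved", flank = NA_character_))
  flank_len <- first_at - 1L + enz[[first_enz]]$cut
  if (flank_len < protocol$min_flank_bp)
    return(list(status = "flank_too_short", flank = NA_character_))
  if (flank_len > protocol$max_fragment_bp)
    return(list(status = "fragment_too_long", flank = NA_character_))
  list(status = "ok", flank = substr(window, 1L, flank_len))
}

#' Simulate an LM-PCR junction library
#'
#' For each integration site, extracts the genomic flank in the site's
#' orientation, simulates the MseI/PstI digest (see [lmpcr_protocol()]), and
#' for recovered fragments emits a read
#' `ltr_primer_nested + flank + revcomp(linker_primer_nested)` with
#' independent per-base substitution errors. Fragment loss (PstI-first
#' cleavage, flank too short/long, no restriction site before the chromosome
#' end) is recorded with a reason code, so that
#' `reads emitted / duplicates + losses = sites`.
#'
#' @param genome Reference genome.
#' @param sites Integration-site data.frame (`chrom`, `pos`, `orient`, and
#'   optionally `cohort`).
#' @param protocol An [lmpcr_protocol()].
#' @param seed Integer seed (drives the error process only; the digest is
#'   deterministic).
#' @return A list of class `lmpcr_library` with elements
#'   \describe{
#'     \item{reads}{data.frame `read_id`, `seq`}
#'     \item{truth}{simulation metadata: `read_id`, `chrom`, `pos`, `orient`,
#'       `cohort`, `flank_len` — never consumed by the pipeline}
#'     \item{losses}{data.frame `site_index`, `chrom`, `pos`, `orient`,
#'       `reason`}
#'   }
#' @export
simulate_lmpcr_reads <- function(genome, sites, protocol, seed) {
  gchr <- .as_genome_chr(genome)
  sites <- .as_sites_df(sites)
  stopifnot(inherits(protocol, "LmPcrProtocol"))
  cohort <- if ("cohort" %in% names(sites)) sites$cohort else
    rep("S", nrow(sites))

  .with_seed(seed, {
    reads <- list(); truth <- list(); losses <- list()
    bases <- c("A", "C", "G", "T")
    p_err <- protocol$per_base_error
    suffix <- .revcomp(protocol$linker_primer_nested)
    for (i in seq_len(nrow(sites))) {
      frag <- .digest_flank(gchr[[sites$chrom[i]]], sites$pos[i],
                            sites$orient[i], protocol)
      if (frag$status != "ok") {
        losses[[length(losses) + 1L]] <- data.frame(
          site_index = i, chrom = sites$chrom[i], pos = sites$pos[i],
          orient = sites$orient[i], reason = frag$status,
          stringsAsFactors = FALSE)
        next
      }
      clean <- paste0(protocol$ltr_primer_nested, frag$flank, suffix)
      for (j in seq_len(protocol$duplicates)) {
        seq <- clean
        if (p_err > 0) {
          ch <- strsplit(seq, "", fixed = TRUE)[[1]]
          hit <- which(stats::runif(length(ch)) < p_err)
          for (h in hit)
            ch[h] <- sample(setdiff(bases, ch[h]), 1L)
          seq <- paste(ch, collapse = "")
        }
        rid <- sprintf("%s_site%05d_r%d", cohort[i], i, j)
        reads[[length(reads) + 1L]] <- data.frame(
          read_id = rid, seq = seq, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          read_id = rid, chrom = sites$chrom[i], pos = sites$pos[i],
          orient = sites$orient[i], cohort = cohort[i],
          flank_len = nchar(frag$flank), stringsAsFactors = FALSE)
      }
    }
    empty_rt <- data.frame(read_id = character(0), seq = character(0))
    structure(list(
      reads = if (length(reads)) do.call(rbind, reads) else empty_rt,
      truth = if (length(truth)) do.call(rbind, truth) else
        data.frame(read_id = character(0), chrom = character(0),
                   pos = integer(0), orient = character(0),
                   cohort = character(0), flank_len = integer(0)),
      losses = if (length(losses)) do.call(rbind, losses) else
        data.frame(site_index = integer(0), chrom = character(0),
                   pos = integer(0), orient = character(0),
                   reason = character(0))),
      class = "lmpcr_library")
  })
}

#' Write / read junction reads as FASTA
#'
#' @param reads A data.frame with `read_id` and `seq` columns (e.g. the
#'   `reads` element of [simulate_lmpcr_reads()]).
#' @param path File path. `read_reads_fasta` also accepts FASTQ input
#'   (`format = "fastq"`); quality strings are read and ignored.
#' @param format `"fasta"` or `"fastq"` (reading only).
#' @return `read_reads_fasta` returns a data.frame with `read_id` and `seq`.
#' @export
write_reads_fasta <- function(reads, path) {
  s <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(s, path, width = 60L)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
read_reads_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  s <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(read_id = sub("\\s.*$", "", names(s)),
             seq = as.character(s), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write the simulation truth side-car
#'
#' Tab-separated metadata recording which site produced each simulated read.
#' Written for test/debug use only; the analysis pipeline never reads it.
#'
#' @param lib An `lmpcr_library`.
#' @param path File path.
#' @export
write_truth_tsv <- function(lib, path) {
  utils::write.table(lib$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
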