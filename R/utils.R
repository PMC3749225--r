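# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  if (length(seed) != 1L || is.na(seed) || !is.numeric(seed))
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Reverse complement of plain character DNA (A/C/G/T only); byte-safe for ASCII.
.revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings.
.hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

.is_dna <- function(x) grepl("^[ACGT]+$", x)

# Normalise a genome (DNAStringSet or named character vector) to a named
# character vector of uppercase chromosome sequences.
.as_genome_chr <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    x <- as.character(genome)
  } else if (is.character(genome)) {
    x <- toupper(genome)
  } else {
    stop("`genome` must be a DNAStringSet or a named character vector",
         call. = FALSE)
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all chromosomes must be named", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("chromosome names must be unique", call. = FALSE)
  bad <- !.is_dna(x)
  if (any(bad))
    stop("chromosome(s) ", paste(names(x)[bad], collapse = ", "),
         " contain characters outside {A,C,G,T}", call. = FALSE)
  x
}

# Standardise a sites data.frame (chrom/pos/orient) and validate values.
.as_sites_df <- function(sites) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "orient")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("`sites` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(sites) && !all(sites$orient %in% c("+", "-")))
    stop("`orient` must be '+' or '-'", call. = FALSE)
  sites
}
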