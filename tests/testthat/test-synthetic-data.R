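# Synthetic genome, annotation, integration-site and LM-PCR library
# generators.

test_that("generated genomes have forced lengths, clean alphabet and are seed-deterministic", {
  g <- generate_genome(1, 100000, gc = 0.5, seed = 7)
  expect_equal(unname(Biostrings::width(g)), 100000)
  expect_true(grepl("^[ACGT]+$", as.character(g)[[1]]))

  g1 <- generate_genome(2, c(50000, 60000), gc = 0.4, seed = 7)
  g2 <- generate_genome(2, c(50000, 60000), gc = 0.4, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- generate_genome(2, c(50000, 60000), gc = 0.4, seed = 8)
  expect_false(identical(as.character(g1), as.character(g3)))

  expect_error(generate_genome(1, 5000, gc = 0.5, seed = 1), "10 kb")
  expect_error(generate_genome(1, 100000, gc = 1.2, seed = 1), "between 0 and 1")
})

test_that("realized GC content matches the target within the binomial 99% band", {
  g <- generate_genome(1, 1000000, gc = 0.5, seed = 7)
  gc_obs <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / 1000000
  # binomial 99% half-width at n = 1e6 is ~0.0013; 0.005 is a safe outer band
  expect_lt(abs(gc_obs - 0.5), 0.005)
})

test_that("generated annotations are disjoint, labelled and reproducible", {
  g <- generate_genome(2, c(100000, 150000), gc = 0.41, seed = 3)

  empty <- generate_annotation(g, 0, c(1000, 2000), 0.1, seed = 4)
  expect_equal(nrow(empty$genes), 0)
  expect_length(empty$label_sets, 0)

  ann <- generate_annotation(g, 50, c(1000, 3000), 0.1, seed = 4)
  expect_equal(nrow(ann$genes), 50)
  expect_length(ann$label_sets$cancer, 5)   # round(0.1 * 50)
  expect_true(all(ann$label_sets$cancer %in% ann$genes$gene_id))
  expect_true(all(ann$genes$strand %in% c("+", "-")))

  # brute-force pairwise overlap sweep
  for (chrom in unique(ann$genes$chrom)) {
    gg <- ann$genes[ann$genes$chrom == chrom, ]
    if (nrow(gg) < 2) next
    for (i in seq_len(nrow(gg) - 1)) for (j in (i + 1):nrow(gg)) {
      expect_true(gg$tx_end[i] <= gg$tx_start[j] ||
                  gg$tx_end[j] <= gg$tx_start[i])
    }
  }

  ann2 <- generate_annotation(g, 50, c(1000, 3000), 0.1, seed = 4)
  expect_identical(ann$genes, ann2$genes)

  # unsatisfiable packing: 30 genes of 10-12 kb cannot fit in 250 kb
  expect_error(
    generate_annotation(g, 30, c(10000, 12000), 0.1, seed = 4,
                        max_attempts = 500),
    "non-overlapping")
})

test_that("TSS positions follow the strand convention", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      strand = c("+", "-"), tx_start = c(100L, 500L),
                      tx_end = c(200L, 900L))
  expect_equal(tss_positions(genes), c(100L, 899L))
})

test_that("integration cohorts follow the TSS mixture and are deterministic", {
  g <- generate_genome(2, c(200000, 300000), gc = 0.41, seed = 5)
  ann <- generate_annotation(g, 6, c(3000, 8000), 0.5, seed = 6)

  # pure TSS component: every site within the window of some TSS
  m1 <- integration_model(1, window_bp = 15000, label = "T")
  s1 <- simulate_integrations(g, ann, 500, m1, seed = 8)
  d1 <- distance_to_nearest_tss(s1, ann)
  expect_true(all(abs(d1$tss_distance) <= 15000))

  # pure background: within-window fraction matches the exact genome
  # coverage of the TSS windows, within a 3.3-sigma binomial band
  m0 <- integration_model(0, window_bp = 15000, label = "U")
  s0 <- simulate_integrations(g, ann, 1000, m0, seed = 9)
  d0 <- distance_to_nearest_tss(s0, ann)
  cvg <- tss_window_coverage(g, ann, 15000)
  frac <- mean(abs(d0$tss_distance) <= 15000, na.rm = TRUE)
  expect_lt(abs(frac - cvg), 3.3 * sqrt(cvg * (1 - cvg) / 1000))

  expect_identical(s0, simulate_integrations(g, ann, 1000, m0, seed = 9))
  expect_false(identical(s0, simulate_integrations(g, ann, 1000, m0,
                                                   seed = 10)))
  expect_false(any(duplicated(paste(s0$chrom, s0$pos))))
  expect_error(
    simulate_integrations(g, genome_annotation(ann$genes[0, ]), 10,
                          m1, seed = 1),
    "at least one gene")
})

test_that("mixture calibration: realized within-window fraction equals pi + (1 - pi) * coverage", {
  g <- generate_genome(2, c(500000, 500000), gc = 0.41, seed = 21)
  ann <- generate_annotation(g, 8, c(4000, 10000), 0.25, seed = 22)
  cvg <- tss_window_coverage(g, ann, 15000)
  for (p in c(0.1, 0.5)) {
    m <- integration_model(p, 15000, "mix")
    s <- simulate_integrations(g, ann, 10000, m, seed = 23)
    frac <- mean(abs(distance_to_nearest_tss(s, ann)$tss_distance) <= 15000)
    expected <- p + (1 - p) * cvg
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_lt(abs(frac - expected), 3 * se)
  }
})

test_that("LM-PCR digestion follows the enzyme rules on planted sequences", {
  prot <- lmpcr_protocol("FV", per_base_error = 0)
  # 10-kb padding with no TTAA/CTGCAG, then planted motifs
  pad <- paste(rep("ACG", 4000), collapse = "")
  # PstI site (CTGCAG) before any MseI site (TTAA): fragment lost
  chrom1 <- paste0(substr(pad, 1, 5000), "CTGCAG", "ACGACG", "TTAA",
                   substr(pad, 1, 5000))
  site <- data.frame(chrom = "c1", pos = 5000L, orient = "+")
  lib <- simulate_lmpcr_reads(c(c1 = chrom1), site, prot, seed = 1)
  expect_equal(nrow(lib$reads), 0)
  expect_equal(lib$losses$reason, "pstI_cleaved")

  # MseI (TTAA) with cut T^TAA at flank offset 30: clean 30-bp flank
  flank30 <- paste0(strrep("ACGGT", 5), "CCCC", "T")  # 30 bp, T at cut
  chrom2 <- paste0(substr(pad, 1, 5000), substr(flank30, 1, 29), "TTAA",
                   substr(pad, 1, 5000))
  site2 <- data.frame(chrom = "c2", pos = 5000L, orient = "+")
  lib2 <- simulate_lmpcr_reads(c(c2 = chrom2), site2, prot, seed = 1)
  expect_equal(nrow(lib2$reads), 1)
  genomic <- substr(chrom2, 5001, 5030)
  expect_identical(
    lib2$reads$seq,
    paste0(prot$ltr_primer_nested, genomic,
           revcomp_chr(prot$linker_primer_nested)))
  expect_equal(lib2$truth$flank_len, 30)

  # with pstI_loss = FALSE the PstI-first fragment is recovered instead
  prot_off <- lmpcr_protocol("FV", per_base_error = 0, pstI_loss = FALSE,
                             min_flank_bp = 5)
  lib3 <- simulate_lmpcr_reads(c(c1 = chrom1), site, prot_off, seed = 1)
  expect_equal(nrow(lib3$reads), 1)
})

test_that("library simulation conserves sites and emits digestion-clean flanks", {
  g <- generate_genome(2, c(150000, 150000), gc = 0.41, seed = 31)
  ann <- generate_annotation(g, 4, c(3000, 6000), 0.5, seed = 32)
  m <- integration_model(0.2, 15000, "FV")
  sites <- simulate_integrations(g, ann, 300, m, seed = 33)
  prot <- lmpcr_protocol("FV", per_base_error = 0)
  lib <- simulate_lmpcr_reads(g, sites, prot, seed = 34)

  # conservation: every input site is either a read or a logged loss
  expect_equal(nrow(lib$reads) / prot$duplicates + nrow(lib$losses), 300)

  # digestion correctness: rescan every emitted flank — no internal MseI
  # cut point and no PstI recognition site survive by construction
  np <- nchar(prot$ltr_primer_nested)
  ns <- nchar(prot$linker_primer_nested)
  flanks <- substr(lib$reads$seq, np + 1, nchar(lib$reads$seq) - ns)
  expect_true(all(nchar(flanks) == lib$truth$flank_len))
  expect_true(all(nchar(flanks) >= prot$min_flank_bp))
  expect_true(all(nchar(flanks) <= prot$max_fragment_bp))
  for (fl in flanks) {
    # an MseI site fully inside the flank would have offered an earlier cut;
    # only the terminal T of the cut T^TAA may remain
    inner <- regexpr("TTAA", substr(fl, 1, nchar(fl) - 1), fixed = TRUE)
    expect_true(inner == -1 || inner + 1 >= nchar(fl))
    expect_equal(unname(regexpr("CTGCAG", fl, fixed = TRUE)[1]), -1)
  }

  # error-free reads are seed-deterministic and relocate to their truth
  lib2 <- simulate_lmpcr_reads(g, sites, prot, seed = 34)
  expect_identical(lib$reads, lib2$reads)
})

test_that("error-free read flanks relocate to their true site by exhaustive search", {
  g <- generate_genome(1, 200000, gc = 0.41, seed = 41)
  ann <- generate_annotation(g, 3, c(3000, 6000), 0.34, seed = 42)
  m <- integration_model(0.1, 15000, "FV")
  prot <- lmpcr_protocol("FV", per_base_error = 0)
  sites <- simulate_integrations(g, ann, 150, m, seed = 43,
                                 protocol = prot)
  lib <- simulate_lmpcr_reads(g, sites, prot, seed = 44)
  expect_equal(nrow(lib$reads), 150)
  np <- nchar(prot$ltr_primer_nested)
  ns <- nchar(prot$linker_primer_nested)
  check <- sample(nrow(lib$reads), 40)
  for (i in check) {
    fl <- substr(lib$reads$seq[i], np + 1, nchar(lib$reads$seq[i]) - ns)
    hit <- bf_map_flank(fl, g, max_mismatches = 0, uniqueness_margin = 1)
    expect_equal(hit$status, "mapped")
    expect_equal(hit$chrom, lib$truth$chrom[i])
    expect_equal(hit$pos, lib$truth$pos[i])
    expect_equal(hit$orient, lib$truth$orient[i])
  }
})
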