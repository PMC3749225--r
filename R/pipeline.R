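# End-to-end orchestration: simulate (or load) -> parse -> map -> collapse
# -> annotate -> compare, as a declarative, seed-reproducible run.

.CONFIG_KEYS <- c("seed", "genome", "annotation", "cohorts", "protocol",
                  "thresholds", "comparisons", "condition_on_recovery",
                  "outdir")
.THRESHOLD_KEYS <- c("tss_window", "label_window", "merge_bp",
                     "max_mismatches", "uniqueness_margin",
                     "max_primer_mismatch", "label_anchor")

.default_thresholds <- function() {
  list(tss_window = 15000L, label_window = 30000L, merge_bp = 3L,
       max_mismatches = 2L, uniqueness_margin = 2L,
       max_primer_mismatch = 1L, label_anchor = "interval")
}

#' Configuration for the Figure-2-style demo analysis
#'
#' A self-contained run config: a 2 x 1 Mb genome with 8 non-overlapping
#' genes (2 labelled cancer), an FV-like cohort (`pi_tss = 0.08`) and an
#' RV-like cohort (`pi_tss = 0.28`), 100 sites each with a 15-kb TSS
#' component, simulated LM-PCR libraries, and Pearson chi-square cohort
#' comparisons of the within-15-kb-of-TSS, within-gene and
#' near-cancer-gene categories.
#'
#' @param seed Integer seed controlling every random stage.
#' @param n Sites per cohort (default 100).
#' @return A config list accepted by [run_pipeline()].
#' @export
figure2_demo_config <- function(seed = 42L, n = 100L) {
  list(
    seed = as.integer(seed),
    genome = list(n_chrom = 2L, lengths = c(1000000L, 1000000L), gc = 0.41),
    annotation = list(n_genes = 8L, gene_len = c(5000L, 20000L),
                      cancer_frac = 0.25),
    cohorts = list(
      list(label = "FV", vector = "FV", pi_tss = 0.08,
           window_bp = 15000L, n = as.integer(n)),
      list(label = "RV", vector = "RV", pi_tss = 0.28,
           window_bp = 15000L, n = as.integer(n))),
    protocol = list(per_base_error = 0.001),
    thresholds = .default_thresholds(),
    comparisons = list(method = "pearson",
                       categories = c("within_tss_window", "in_gene",
                                      "within_cancer")),
    condition_on_recovery = TRUE,
    outdir = NULL)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_pipeline()]'s config.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

.build_protocol <- function(cohort, overrides) {
  vec <- cohort$vector %||% (if (cohort$label %in% c("FV", "RV"))
    cohort$label else "FV")
  args <- c(list(vector = vec), overrides)
  do.call(lmpcr_protocol, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full integration-site analysis pipeline
#'
#' Executes, per cohort: site simulation (or junction-read loading), LM-PCR
#' library simulation, junction parsing, flank mapping, collapse to
#' independent sites, site classification and the TSS-centred density
#' profile; then compares cohorts category-by-category with
#' [compare_categories()]. Deterministic given the config (including its
#' seed): rerunning a config reproduces the report byte-for-byte.
#'
#' Config fields (all thresholds optional, defaults as in the module
#' functions):
#' \describe{
#'   \item{seed}{integer; mandatory when any cohort is simulated.}
#'   \item{genome}{either `list(fasta = path)` or simulation parameters
#'     `list(n_chrom, lengths, gc)`.}
#'   \item{annotation}{either `list(bed = path, labels = c(label = path))`
#'     or `list(n_genes, gene_len, cancer_frac)`.}
#'   \item{cohorts}{list of cohorts; each has `label`, optional `vector`
#'     (`"FV"`/`"RV"`, selects primers), and exactly one of `reads` (FASTA
#'     path) or simulation parameters `pi_tss`, `window_bp`, `n_sites`
#'     (optional per-cohort `seed`). Note for YAML configs: the key is
#'     `n_sites`, not `n`, because YAML 1.1 parses a bare `n` as a boolean.}
#'   \item{protocol}{named overrides passed to [lmpcr_protocol()].}
#'   \item{thresholds}{`tss_window`, `label_window`, `merge_bp`,
#'     `max_mismatches`, `uniqueness_margin`, `max_primer_mismatch`,
#'     `label_anchor`.}
#'   \item{comparisons}{`method` and `categories` (classification column
#'     names) compared between the first two cohorts.}
#'   \item{condition_on_recovery}{if `TRUE`, simulated sites are redrawn
#'     until LM-PCR-recoverable (see [simulate_integrations()]).}
#'   \item{outdir}{if non-`NULL`, writes the annotation BED, per-cohort
#'     site TSVs, profile TSVs and the JSON report there.}
#' }
#'
#' @param config A config list, e.g. from [figure2_demo_config()] or
#'   [read_run_config()].
#' @return A `run_report` list: resolved config, genome summary, TSS-window
#'   genome coverage, per-cohort stage counts / category fractions /
#'   density profile, and the contingency comparisons.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  bad <- setdiff(names(config), .CONFIG_KEYS)
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$cohorts) || !length(config$cohorts))
    stop("config must define at least one cohort", call. = FALSE)
  th <- utils::modifyList(.default_thresholds(),
                          config$thresholds %||% list())
  bad_th <- setdiff(names(th), .THRESHOLD_KEYS)
  if (length(bad_th))
    stop("invalid threshold key(s): ", paste(bad_th, collapse = ", "),
         call. = FALSE)
  simulating <- any(vapply(config$cohorts,
                           function(co) is.null(co$reads), logical(1)))
  if ((simulating || is.null(config$genome$fasta)) && is.null(config$seed))
    stop("config key 'seed' is mandatory when simulating", call. = FALSE)
  seed <- as.integer(config$seed %||% 0L)

  # --- genome ---------------------------------------------------------
  gcfg <- config$genome %||% list()
  genome <- if (!is.null(gcfg$fasta)) {
    if (!file.exists(gcfg$fasta))
      stop("genome fasta not found: ", gcfg$fasta, call. = FALSE)
    read_genome_fasta(gcfg$fasta)
  } else {
    generate_genome(gcfg$n_chrom %||% 2L,
                    gcfg$lengths %||% 1000000L,
                    gcfg$gc %||% 0.41, seed = seed + 11L)
  }
  gchr <- .as_genome_chr(genome)

  # --- annotation -----------------------------------------------------
  acfg <- config$annotation %||% list()
  ann <- if (!is.null(acfg$bed)) {
    if (!file.exists(acfg$bed))
      stop("annotation bed not found: ", acfg$bed, call. = FALSE)
    read_annotation_bed(acfg$bed, unlist(acfg$labels %||% character(0)))
  } else {
    generate_annotation(genome,
                        acfg$n_genes %||% 8L,
                        unlist(acfg$gene_len %||% c(5000L, 20000L)),
                        acfg$cancer_frac %||% 0.25, seed = seed + 23L)
  }
  coverage <- tss_window_coverage(genome, ann, th$tss_window)

  # --- per-cohort stages ----------------------------------------------
  cohort_reports <- list()
  classified <- list()
  for (ci in seq_along(config$cohorts)) {
    co <- config$cohorts[[ci]]
    if (is.null(co$label)) stop("every cohort needs a 'label'", call. = FALSE)
    has_reads <- !is.null(co$reads)
    has_sim <- !is.null(co$pi_tss)
    if (has_reads == has_sim)
      stop("cohort '", co$label, "' must define exactly one of 'reads' or ",
           "simulation parameters (pi_tss, window_bp, n)", call. = FALSE)
    protocol <- .build_protocol(co, config$protocol %||% list())
    counts <- list()
    if (has_sim) {
      co_seed <- as.integer(co$seed %||% (seed + 100L * ci + 1L))
      model <- integration_model(co$pi_tss, co$window_bp %||% 15000L,
                                 co$label)
      n_sites <- co$n_sites %||% co$n
      if (is.null(n_sites))
        stop("cohort '", co$label, "' needs 'n_sites'", call. = FALSE)
      sites <- simulate_integrations(
        genome, ann, n_sites, model, seed = co_seed,
        protocol = if (isTRUE(config$condition_on_recovery)) protocol else NULL)
      lib <- simulate_lmpcr_reads(genome, sites, protocol,
                                  seed = co_seed + 1L)
      reads <- lib$reads
      counts$sites_simulated <- nrow(sites)
      counts$losses <- as.list(table(lib$losses$reason))
      counts$losses_total <- nrow(lib$losses)
    } else {
      if (!file.exists(co$reads))
        stop("reads file not found for cohort '", co$label, "': ", co$reads,
             call. = FALSE)
      fmt <- if (grepl("\\.f(ast)?q$", co$reads, ignore.case = TRUE))
        "fastq" else "fasta"
      reads <- read_reads_fasta(co$reads, format = fmt)
    }
    counts$reads <- nrow(reads)

    calls <- parse_junction_reads(reads, protocol, th$max_primer_mismatch)
    counts$parse <- as.list(table(calls$status))
    ok <- calls[calls$status == "ok", , drop = FALSE]

    mapping <- map_flanks(ok, genome, th$max_mismatches,
                          th$uniqueness_margin)
    counts$mapping <- as.list(table(mapping$status))
    mapped <- mapping[mapping$status == "mapped", , drop = FALSE]

    indep <- collapse_to_independent_sites(mapped, th$merge_bp)
    counts$independent_sites <- nrow(indep)

    cls <- classify_sites(indep, ann, th$tss_window, th$label_window,
                          th$label_anchor)
    classified[[co$label]] <- cls
    frac_cols <- c("in_gene", "within_tss_window",
                   paste0("within_", names(ann$label_sets)))
    fractions <- lapply(frac_cols, function(col)
      if (nrow(cls)) 100 * mean(cls[[col]]) else NA_real_)
    names(fractions) <- paste0(frac_cols, "_pct")

    profile <- tss_density_profile(indep, ann)
    cohort_reports[[co$label]] <- list(
      counts = counts, fractions = fractions,
      profile = profile$bins,
      profile_total_sites = profile$total_sites)
  }

  # --- comparisons ----------------------------------------------------
  comparisons <- list()
  ccfg <- config$comparisons %||% list()
  categories <- ccfg$categories %||% "within_tss_window"
  method <- ccfg$method %||% "pearson"
  if (length(classified) >= 2L) {
    la <- names(classified)[1]; lb <- names(classified)[2]
    for (cat in categories) {
      ca <- classified[[la]]; cb <- classified[[lb]]
      if (!cat %in% names(ca)) next
      res <- compare_categories(sum(ca[[cat]]), nrow(ca),
                                sum(cb[[cat]]), nrow(cb), method = method)
      comparisons[[cat]] <- list(
        category = cat, cohort_a = la, cohort_b = lb, method = method,
        k_a = sum(ca[[cat]]), n_a = nrow(ca),
        k_b = sum(cb[[cat]]), n_b = nrow(cb),
        statistic = res$statistic, df = res$df, p_value = res$p_value)
    }
  }

  report <- structure(list(
    config = utils::modifyList(config, list(thresholds = th)),
    genome = list(n_chrom = length(gchr),
                  lengths = as.integer(nchar(gchr))),
    n_genes = nrow(ann$genes),
    tss_window_coverage = coverage,
    cohorts = cohort_reports,
    comparisons = comparisons), class = "run_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_bed(ann, file.path(config$outdir, "annotation.bed"))
    for (lab in names(classified)) {
      utils::write.table(classified[[lab]],
                         file.path(config$outdir,
                                   paste0("sites_", lab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cohort_reports[[lab]]$profile,
                         file.path(config$outdir,
                                   paste0("profile_", lab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_run_report(report, file.path(config$outdir, "report.json"))
  }
  report
}

#' Serialize a run report as JSON
#'
#' Deterministic: contains no timestamps, so identical configs produce
#' byte-identical files.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path File path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Integration-site pipeline report\n")
  cat("  genome:", x$genome$n_chrom, "chromosome(s),",
      sum(x$genome$lengths), "bp;", x$n_genes, "genes\n")
  cat("  TSS-window genome coverage:",
      format(100 * x$tss_window_coverage, digits = 3), "%\n")
  for (lab in names(x$cohorts)) {
    co <- x$cohorts[[lab]]
    cat("  cohort ", lab, ": ", co$counts$independent_sites,
        " independent sites; within TSS window ",
        format(co$fractions$within_tss_window_pct, digits = 3), "%\n",
        sep = "")
  }
  for (cmp in x$comparisons)
    cat("  ", cmp$category, " (", cmp$cohort_a, " ", cmp$k_a, "/", cmp$n_a,
        " vs ", cmp$cohort_b, " ", cmp$k_b, "/", cmp$n_b, "): p = ",
        format(cmp$p_value, digits = 4), " [", cmp$method, "]\n", sep = "")
  invisible(x)
}
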