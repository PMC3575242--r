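## Orchestration: strip -> diversity -> phi -> max-chi2 -> Rm/Rh ->
## fragment scan -> fragment trees -> parental assignment -> RFLP, from a
## single seeded config, with machine-readable outputs. Each stage is
## recorded in the run report as computed or skipped-with-reason; the
## report is free of timestamps so a fixed seed gives byte-identical
## output.

#' Build a run configuration
#'
#' Either `alignment` (a path or an `aln`) or `simulation` (a
#' [sim_config()], run through [simulate_mosaic_scenario()]) must be given.
#'
#' @param alignment aligned FASTA path or `aln` object, or `NULL`.
#' @param partition optional partition map (path or `partition_map`).
#' @param groups optional group map (2-column TSV path `id<TAB>group`, or a
#'   named character vector).
#' @param simulation optional [sim_config()].
#' @param n_recombinants mosaics to simulate (simulation runs only).
#' @param half_widths,n_perm,alpha max-chi2 scan parameters.
#' @param phi_window,phi_perm PHI test parameters.
#' @param run_rflp attempt in-silico PCR-RFLP typing of the input
#'   sequences.
#' @param seed global seed; per-stage seeds are derived from it by stable
#'   hashing of stage names.
#' @param outdir output directory (created); `NULL` for no file output.
#' @return a `run_config` list (validated).
#' @export
run_config <- function(alignment = NULL, partition = NULL, groups = NULL,
                       simulation = NULL, n_recombinants = 10L,
                       half_widths = c(70L, 80L, 90L, 100L),
                       n_perm = 10000L, alpha = 0.05,
                       phi_window = 100L, phi_perm = 1000L,
                       run_rflp = FALSE, seed = 1L, outdir = NULL) {
  if (is.null(alignment) && is.null(simulation))
    te_stop("config needs an alignment or a simulation block", "config_error")
  if (is.character(alignment) && !file.exists(alignment))
    te_stop(paste0("alignment file not found: ", alignment), "config_error")
  if (is.character(partition) && !file.exists(partition))
    te_stop(paste0("partition file not found: ", partition), "config_error")
  if (is.character(groups) && !file.exists(groups))
    te_stop(paste0("group map not found: ", groups), "config_error")
  structure(list(alignment = alignment, partition = partition, groups = groups,
                 simulation = simulation, n_recombinants = as.integer(n_recombinants),
                 half_widths = as.integer(half_widths),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 phi_window = as.integer(phi_window),
                 phi_perm = as.integer(phi_perm),
                 run_rflp = isTRUE(run_rflp), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys mirror [run_config()] arguments (the
#'   `simulation` block holds [sim_config()] fields).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  do.call(run_config, y)
}

## stable per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' @param cfg a [run_config()].
#' @return a `run_report` list: `versions`, `config`, one entry per stage
#'   (`diversity`, `phi`, `maxchi`, `events`, `rm`, `rh`, `fragment_scan`,
#'   `trees`, `assignments`, `rflp`), and `warnings`. Skipped stages carry
#'   a `skipped` reason. With `outdir` set, artifacts (FASTA/TSV/JSON/
#'   newick/BED) are written there, including `report.json`.
#' @export
run_pipeline <- function(cfg) {
  warn_log <- character()
  note <- function(...) message("[temosaic] ", sprintf(...))
  capture_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  report <- list(versions = list(
    temosaic = as.character(utils::packageVersion("temosaic")),
    R = paste(R.version$major, R.version$minor, sep = ".")))

  ## ---- inputs ----
  groups <- cfg$groups
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    note("simulating mosaic scenario (seed %d)", cfg$seed)
    scen <- simulate_mosaic_scenario(cfg$simulation,
                                     n_recombinants = cfg$n_recombinants,
                                     seed = stage_seed(cfg$seed, "simulate"))
    aln <- scen$alignment
    truth <- scen$truth
    if (is.null(groups)) groups <- scen$groups
    report$simulation <- list(n_sequences = n_seq(aln),
                              planted = scen$planted)
  } else {
    aln <- if (inherits(cfg$alignment, "aln")) cfg$alignment
           else read_alignment(cfg$alignment)
    note("read alignment: %d sequences x %d columns", n_seq(aln), n_col(aln))
  }
  if (is.character(groups) && length(groups) == 1L && is.null(names(groups))) {
    gm <- utils::read.delim(groups, header = FALSE, stringsAsFactors = FALSE)
    groups <- stats::setNames(gm[[2L]], gm[[1L]])
  }
  part <- cfg$partition
  if (is.character(part)) part <- read_partition_map(part)

  stripped <- capture_warnings(strip_columns(aln))
  report$alignment <- list(n = n_seq(aln), L_source = n_col(aln),
                           L_stripped = n_col(stripped))

  ## ---- diversity ----
  report$diversity <- capture_warnings(tryCatch({
    div <- list(pi = nucleotide_diversity(stripped),
                theta_w = watterson_theta(stripped),
                S = segregating_sites(stripped),
                mean_similarity = mean_similarity(stripped))
    if (!is.null(part))
      div$partitions <- as.data.frame(partition_diversity(aln, part))
    div
  }, temosaic_error = function(e) list(skipped = conditionMessage(e))))

  ## ---- phi ----
  phi <- capture_warnings(phi_test(stripped, window_w = cfg$phi_window,
                                   n_perm = cfg$phi_perm,
                                   seed = stage_seed(cfg$seed, "phi")))
  report$phi <- unclass(phi)

  ## ---- max-chi2 ----
  note("max-chi2 scan (%d permutations)", cfg$n_perm)
  calls <- capture_warnings(tryCatch(
    maxchi_scan(stripped, half_widths = cfg$half_widths, n_perm = cfg$n_perm,
                alpha = cfg$alpha, seed = stage_seed(cfg$seed, "maxchi")),
    temosaic_error = function(e) NULL))
  if (is.null(calls)) {
    report$maxchi <- list(skipped = "scan not applicable")
    events <- merge_calls(structure(data.frame(), class = c("breakpoint_calls", "data.frame")))
    report$events <- list(skipped = "no calls")
  } else {
    report$maxchi <- list(n_calls = nrow(calls), calls = as.data.frame(calls),
                          skipped_pairs = attr(calls, "skipped"))
    events <- merge_calls(calls)
    report$events <- as.data.frame(events)
  }

  ## ---- Rm / Rh ----
  rm_res <- hudson_kaplan_rm(stripped)
  rh_res <- haplotype_bound_rh(stripped)
  report$rm <- list(rm = rm_res$rm, n_sites = rm_res$n_sites)
  report$rh <- list(rh = rh_res$rh)

  ## ---- fragment scan + trees ----
  scan_bp <- capture_warnings(fragment_scan(stripped))
  report$fragment_scan <- list(breakpoints = as.integer(scan_bp))
  trees <- capture_warnings(fragment_trees(stripped, scan_bp))
  report$trees <- list(n_fragments = length(trees),
                       newick = vapply(trees, ape::write.tree, character(1)))

  ## ---- parental assignment ----
  if (is.null(groups)) {
    report$assignments <- list(skipped = "no group map provided")
  } else {
    recombs <- if (!is.null(truth)) {
      seg_counts <- table(truth$seq_id)
      names(seg_counts)[seg_counts > 1L]
    } else if (!is.null(calls) && nrow(calls)) {
      unique(c(calls$seq1, calls$seq2))
    } else character()
    recombs <- intersect(recombs, aln_ids(stripped))
    frag_spans <- attr(trees, "fragments")
    frag_dists <- capture_warnings(lapply(names(trees), function(nm) {
      span <- as.integer(strsplit(nm, "-")[[1L]])
      pairwise_distances(extract_span(stripped, span[1L], span[2L]), "p")
    }))
    asn <- list()
    for (rid in recombs) {
      a <- tryCatch(assign_parents(rid, frag_dists, groups),
                    temosaic_error = function(e) NULL)
      if (!is.null(a))
        asn[[rid]] <- data.frame(recomb_id = rid, assignment = a$assignment,
                                 stringsAsFactors = FALSE)
    }
    report$assignments <- if (length(asn)) do.call(rbind, asn)
                          else list(skipped = "no recombinant sequences identified")
  }

  ## ---- RFLP ----
  if (!cfg$run_rflp) {
    report$rflp <- list(skipped = "disabled in config")
  } else {
    seqs <- aln_strings(aln)
    codes <- lapply(seqs, function(s) rflp_type(s))
    got <- !vapply(codes, is.null, logical(1))
    if (!any(got)) {
      report$rflp <- list(skipped = "no amplicons found (primer sites absent)")
    } else {
      tab <- data.frame(id = names(seqs)[got],
                        code = vapply(codes[got], `[[`, integer(1), "code"),
                        stringsAsFactors = FALSE)
      iso <- sub("_.*$", "", tab$id)
      summ <- isolate_summary(split(tab$code, iso))
      report$rflp <- list(typed = tab, summary = list(
        mean = summ$mean, sd = summ$sd, max = summ$max))
    }
  }

  report$warnings <- warn_log
  report$config <- unclass(cfg)
  report$config$outdir <- NULL          # run location, not part of the analysis
  report$config$alignment <- if (is.character(cfg$alignment)) cfg$alignment
                             else if (!is.null(cfg$alignment)) "<in-memory alignment>"
  report$config$simulation <- if (!is.null(cfg$simulation)) unclass(cfg$simulation)
  class(report) <- "run_report"

  if (!is.null(cfg$outdir)) write_report_files(report, stripped, truth,
                                               calls, events, trees, cfg)
  report
}

## internal: write all artifacts under cfg$outdir
write_report_files <- function(report, stripped, truth, calls, events, trees,
                               cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$outdir, f)
  write_alignment(stripped, p("alignment_stripped.fasta"))
  if (!is.null(truth)) write_truth(truth, p("truth.tsv"))
  if (!is.null(calls) && nrow(calls)) write_calls(calls, p("calls.tsv"))
  if (nrow(events)) {
    utils::write.table(as.data.frame(events), p("events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_events_bed(events, p("events.bed"))
  }
  if (length(trees)) write_trees(trees, p("trees.nwk"))
  if (is.data.frame(report$assignments))
    utils::write.table(report$assignments, p("assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(cfg$outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("temosaic run report\n")
  cat(sprintf("  alignment: %d sequences, %d/%d columns kept\n",
              x$alignment$n, x$alignment$L_stripped, x$alignment$L_source))
  if (is.null(x$diversity$skipped))
    cat(sprintf("  pi = %.4f, theta_w = %.4f, S = %d\n",
                x$diversity$pi, x$diversity$theta_w, x$diversity$S))
  if (isTRUE(x$phi$testable))
    cat(sprintf("  phi test: p = %.4g\n", x$phi$p_value))
  if (is.null(x$maxchi[["skipped"]]))
    cat(sprintf("  max-chi2: %d calls, %d merged events\n", x$maxchi$n_calls,
                if (is.data.frame(x$events)) nrow(x$events) else 0L))
  cat(sprintf("  Rm = %d, Rh = %d\n", x$rm$rm, x$rh$rh))
  invisible(x)
}
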