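#' The 43-protein two-state folding core table
#'
#' Loads the packaged transcription of a published compilation of 43
#' unique two-state folding proteins: chain length, total contact count
#' (6 Angstrom heavy-atom cutoff, separation >= 3), the size of the
#' locks-plus-neighbours core (residues and contacts), and the natural
#' log of the experimental folding rate.
#'
#' @return Tibble with columns `protein_id`, `residues`, `contacts`,
#'   `core_residues`, `core_contacts`, `ln_kf`.
#' @export
#' @examples
#' summarize_core_stats(two_state_cores())
two_state_cores <- function() {
  path <- system.file("extdata", "two_state_cores.tsv",
                      package = "loopnlock", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Summarise the extent of locks-plus-neighbours cores
#'
#' From a per-protein table of total and core residue/contact counts,
#' computes the mean core sizes, the aggregate core percentages (ratios
#' of column sums), and the per-protein core-residue proportion with its
#' mean, s.d. and extremes.
#'
#' @param records Tibble with columns `protein_id`, `residues`,
#'   `contacts`, `core_residues`, `core_contacts` (and optionally
#'   `ln_kf`).
#' @return List of class `ln_core_summary`: `summary` (one-row tibble
#'   with `mean_core_contacts`, `mean_core_residues`,
#'   `pct_core_contacts`, `pct_core_residues`, `mean_residue_pct`,
#'   `sd_residue_pct`, `min_residue_pct`, `max_residue_pct`) and
#'   `per_protein` (the input with `residue_pct` and `contact_pct`
#'   columns added).
#' @export
summarize_core_stats <- function(records) {
  needed <- c("protein_id", "residues", "contacts", "core_residues",
              "core_contacts")
  missing <- setdiff(needed, names(records))
  stop_unless(length(missing) == 0, "records lack column(s): %s",
              paste(missing, collapse = ", "))
  per <- dplyr::mutate(tibble::as_tibble(records),
                       residue_pct = 100 * .data$core_residues /
                         .data$residues,
                       contact_pct = 100 * .data$core_contacts /
                         .data$contacts)
  summary <- tibble::tibble(
    n_proteins = nrow(per),
    mean_core_contacts = mean(per$core_contacts),
    mean_core_residues = mean(per$core_residues),
    pct_core_contacts = 100 * sum(per$core_contacts) / sum(per$contacts),
    pct_core_residues = 100 * sum(per$core_residues) / sum(per$residues),
    mean_residue_pct = mean(per$residue_pct),
    sd_residue_pct = if (nrow(per) > 1) sd(per$residue_pct) else NA_real_,
    min_residue_pct = min(per$residue_pct),
    max_residue_pct = max(per$residue_pct))
  structure(list(summary = summary, per_protein = per),
            class = "ln_core_summary")
}

#' @export
print.ln_core_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<core summary> %d proteins\n",
           "  mean core: %.1f contacts, %.1f residues\n",
           "  aggregate core share: %.1f%% of contacts, %.1f%% of residues\n",
           "  per-protein core residues: %.1f +/- %.1f%% (range %.1f-%.1f%%)\n"),
    s$n_proteins, s$mean_core_contacts, s$mean_core_residues,
    s$pct_core_contacts, s$pct_core_residues, s$mean_residue_pct,
    s$sd_residue_pct, s$min_residue_pct, s$max_residue_pct))
  invisible(x)
}

default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = tempfile("loopnlock_run"),
    stages = list(synth = TRUE, loops = TRUE, metrics = TRUE,
                  control = FALSE),
    synth = list(n_proteins = 8, n_residues = c(60, 110)),
    loops = list(window = 1, min_score = 0.25),
    metrics = list(slope = -100, intercept = 10, noise_sd = 0.5),
    control = list(n_reps = 200),
    rates_file = NULL
  )
}

validate_config <- function(config) {
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  stop_unless(is.numeric(config$seed) && length(config$seed) == 1,
              "config error [global]: seed must be a single number")
  stop_unless(is.character(config$out_dir),
              "config error [global]: out_dir must be a path")
  if (isTRUE(config$stages$metrics) && !isTRUE(config$stages$synth) &&
        is.null(config$rates_file)) {
    abort("config error [metrics]: stage enabled but no rate source (enable synth or set rates_file)")
  }
  config
}

#' Run the synthetic closed-loop pipeline end to end
#'
#' Orchestrates generation, loop finding, core construction, metric
#' computation, rate correlation and (optionally) the random-contact
#' control, in dependency order, writing per-stage TSV/JSON artifacts and
#' a structured run log (parameters, seeds, output digests) to
#' `out_dir`. Reruns with the same config are byte-identical.
#'
#' @param config Named list (merged over documented defaults) or path to
#'   a YAML file. Keys: `seed`, `out_dir`, `stages` (logical toggles
#'   `synth`, `loops`, `metrics`, `control`), `synth`
#'   (`n_proteins`, `n_residues` range), `loops` (`window`,
#'   `min_score`), `metrics` (`slope`, `intercept`, `noise_sd`),
#'   `control` (`n_reps`), `rates_file` (TSV with `protein_id`, `ln_kf`;
#'   required if `metrics` runs without `synth`).
#' @return Invisibly, a list with the per-stage results and the log.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  results <- list()
  emit <- function(stage, params, files) {
    digests <- tools::md5sum(file.path(config$out_dir, files))
    log[[stage]] <<- list(stage = stage, params = params,
                          outputs = as.list(digests))
  }

  if (isTRUE(config$stages$synth)) {
    cohort <- synth_folding_cohort(
      n_proteins = config$synth$n_proteins, seed = config$seed,
      n_residues = seq(config$synth$n_residues[1],
                       config$synth$n_residues[2]))
    rates <- make_rate_table(cohort, slope = config$metrics$slope,
                             intercept = config$metrics$intercept,
                             noise_sd = config$metrics$noise_sd,
                             metric = "tcd_core",
                             seed = derive_seed(config$seed, 101))
    readr::write_tsv(rates, file.path(config$out_dir, "rates.tsv"))
    contacts_tbl <- purrr::map_dfr(seq_len(nrow(cohort)), function(p)
      dplyr::mutate(tibble::as_tibble(cohort$contacts[[p]]),
                    protein_id = cohort$protein_id[p], .before = 1))
    readr::write_tsv(contacts_tbl, file.path(config$out_dir,
                                             "contacts.tsv"))
    results$cohort <- cohort
    results$rates <- rates
    emit("synth", config$synth, c("rates.tsv", "contacts.tsv"))
  }

  if (isTRUE(config$stages$loops)) {
    stop_unless(!is.null(results$cohort),
                "stage error [loops]: no structures (enable synth)")
    loops_tbl <- purrr::map_dfr(seq_len(nrow(results$cohort)),
                                function(p) {
      fl <- find_loops(results$cohort$structure[[p]],
                       window = config$loops$window,
                       min_score = config$loops$min_score)
      if (nrow(fl) == 0) return(tibble::tibble())
      tibble::tibble(protein_id = results$cohort$protein_id[p],
                     loop = fl$loop, start = fl$start, end = fl$end,
                     length = fl$length, score = fl$score,
                     lock_start = purrr::map_chr(fl$lock_start,
                                                 paste, collapse = ","),
                     lock_end = purrr::map_chr(fl$lock_end, paste,
                                               collapse = ","),
                     pair_start = fl$pair_start, pair_end = fl$pair_end)
    })
    readr::write_tsv(loops_tbl, file.path(config$out_dir, "loops.tsv"))
    results$loops <- loops_tbl
    emit("loops", config$loops, "loops.tsv")
  }

  if (isTRUE(config$stages$metrics)) {
    cohort <- results$cohort
    rates <- results$rates %||%
      readr::read_tsv(config$rates_file, show_col_types = FALSE)
    cores <- purrr::map(seq_len(nrow(cohort)), function(p) {
      lp <- results$loops
      mine <- lp[lp$protein_id == cohort$protein_id[p], , drop = FALSE]
      if (nrow(mine) == 0) return(NULL)
      build_core(c(mine$pair_start, mine$pair_end), cohort$contacts[[p]])
    })
    metrics_tbl <- purrr::map_dfr(seq_len(nrow(cohort)), function(p) {
      full <- contact_metrics(cohort$contacts[[p]], subset = "all",
                              protein_id = cohort$protein_id[p])
      core <- if (!is.null(cores[[p]]) && nrow(cores[[p]]$contacts) > 0)
        contact_metrics(cores[[p]]$contacts, L = cohort$L[p],
                        subset = "core",
                        protein_id = cohort$protein_id[p])
      dplyr::bind_rows(full, core)
    })
    readr::write_tsv(metrics_tbl, file.path(config$out_dir,
                                            "metrics.tsv"))
    corr <- purrr::map(c(all = "all", core = "core"), function(sub) {
      vals <- metrics_tbl |>
        dplyr::filter(.data$metric == "TCD", .data$subset == sub) |>
        dplyr::select("protein_id", "value")
      if (nrow(vals) < 3) return(NULL)
      correlate_lnkf(vals, rates)
    })
    jsonlite::write_json(
      purrr::map(purrr::compact(corr), function(cc)
        list(r2 = cc$r2, slope = cc$slope, intercept = cc$intercept,
             n = cc$n)),
      file.path(config$out_dir, "correlation.json"),
      auto_unbox = TRUE, digits = NA)
    results$metrics <- metrics_tbl
    results$correlations <- corr
    results$cores <- cores
    emit("metrics", config$metrics,
         c("metrics.tsv", "correlation.json"))
  }

  if (isTRUE(config$stages$control)) {
    cohort <- results$cohort
    k <- purrr::map_int(results$cores, function(co)
      if (is.null(co)) 0L else nrow(co$contacts))
    names(k) <- cohort$protein_id
    usable <- k > 0
    ctrl <- random_contact_control(
      cohort[usable, , drop = FALSE], results$rates,
      k[usable], n_reps = config$control$n_reps,
      seed = derive_seed(config$seed, 202),
      observed_r2 = results$correlations$core$r2)
    jsonlite::write_json(
      list(observed_r2 = ctrl$observed_r2,
           empirical_p = ctrl$empirical_p,
           null_r2_mean = mean(ctrl$null_r2)),
      file.path(config$out_dir, "control.json"), auto_unbox = TRUE,
      digits = NA)
    results$control <- ctrl
    emit("control", config$control, "control.json")
  }

  log$run <- list(package_version =
                    as.character(utils::packageVersion("loopnlock")),
                  seed = config$seed)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(log = log, config = config)))
}
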