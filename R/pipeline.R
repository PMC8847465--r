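# Pipeline orchestration: call -> select -> type -> duration, with tabular
# reports (TSV) and a JSON run summary.

#' Pipeline thresholds and options
#'
#' @param u Optional background-rate override (mutations/kb/period); when
#'   `NULL` the rate is estimated from qualifying introns.
#' @param theta,min_sites,ancient_max,type8_5prime,type8_coding Gene-typing
#'   thresholds (see [typing_config()]).
#' @param iqr_mult Outlier fence multiplier for duration-locus selection.
#' @param exclude_loci Manual exclusion list for the duration estimator.
#' @param include_recurrent Count recurrent-suspect events into phase counts.
#' @return Named list of options.
#' @export
pipeline_config <- function(u = NULL, theta = 0.9, min_sites = 3,
                            ancient_max = 1, type8_5prime = 5,
                            type8_coding = 2, iqr_mult = 3,
                            exclude_loci = character(0),
                            include_recurrent = FALSE) {
  stopifnot(theta > 0, min_sites > 0, type8_5prime > 0, type8_coding > 0,
            iqr_mult > 0)
  list(u = u, theta = theta, min_sites = min_sites,
       ancient_max = ancient_max, type8_5prime = type8_5prime,
       type8_coding = type8_coding, iqr_mult = iqr_mult,
       exclude_loci = exclude_loci, include_recurrent = include_recurrent)
}

#' Read a YAML run configuration
#'
#' Recognized keys: `input_dir`, `output_dir`, `role_map` (named list),
#' `thresholds` (any [pipeline_config()] field) and `seed`.
#'
#' @param path YAML file.
#' @return List with `input_dir`, `output_dir`, `role_map`, `seed` and
#'   `config` ([pipeline_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$thresholds %||% list()
  cfg <- do.call(pipeline_config, th)
  list(input_dir = y$input_dir, output_dir = y$output_dir,
       role_map = unlist(y$role_map), seed = y$seed, config = cfg)
}

#' Call and classify mutations for every locus of a dataset
#'
#' @param dataset A `ggm_dataset` (or any list of locus objects under
#'   `$loci`).
#' @return Classified event data frame for all loci and regions.
#' @export
classify_dataset <- function(dataset) {
  loci <- dataset$loci
  evs <- lapply(loci, function(lc) {
    rbind(call_mutations(lc$five_prime, lc$annotation),
          call_mutations(lc$coding, lc$annotation))
  })
  ev <- do.call(rbind, evs)
  rownames(ev) <- NULL
  normalize_events(ev)
}

#' Run the full analysis pipeline
#'
#' Executes mutation calling, phase counting, selection scanning, gene
#' typing and duration estimation in order, and writes the report files:
#' `events.tsv`, `phase_counts.tsv`, `background_rates.tsv`,
#' `selection_calls.tsv`, `selection_summary.tsv`, `gene_types.tsv`,
#' `type_census.json`, `duration.json`, `manhattan.tsv` and
#' `run_summary.json` (config echo, hash and per-stage counts). Reruns on
#' the same inputs and configuration are byte-identical: no stage after
#' simulation draws random numbers.
#'
#' @param dataset A `ggm_dataset` or a dataset directory path.
#' @param out_dir Report directory (created if needed).
#' @param config [pipeline_config()].
#' @return Invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(dataset, out_dir = NULL,
                         config = pipeline_config()) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ggm_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "ggm_pipeline_error")
    })
  }
  events <- stage("call", classify_dataset(dataset))
  counts <- stage("count", count_by_phase(events, config$include_recurrent))
  sel <- stage("select", selection_scan(dataset$loci, events, u = config$u))
  sel_sum <- summarize_selection(sel$calls)
  tcfg <- typing_config(theta = config$theta, min_sites = config$min_sites,
                        ancient_max = config$ancient_max,
                        type8_5prime = config$type8_5prime,
                        type8_coding = config$type8_coding)
  types <- stage("type", gene_type_calls(events, tcfg))
  census <- type_census(types$table)
  dur <- stage("duration", list(
    five_prime = duration_estimate(
      counts[counts$region_kind == "five_prime", , drop = FALSE],
      "five_prime", config$iqr_mult, config$exclude_loci),
    coding = duration_estimate(
      counts[counts$region_kind == "coding_genomic", , drop = FALSE],
      "coding", config$iqr_mult, config$exclude_loci)))

  chrom <- vapply(dataset$loci, function(lc) {
    lc$chromosome %||% lc$annotation$chromosome %||% NA_character_
  }, "")
  names(chrom) <- vapply(dataset$loci, `[[`, "", "locus_id")
  crop_ev <- events[events$category %in%
                      c("early_phase1", "lineage_indica",
                        "lineage_japonica"), , drop = FALSE]
  manhattan <- data.frame(
    locus_id = crop_ev$locus_id,
    chromosome = unname(chrom[crop_ev$locus_id]),
    region = crop_ev$region_kind,
    position = crop_ev$start,
    category = crop_ev$category,
    count = crop_ev$multiplicity,
    stringsAsFactors = FALSE)
  manhattan <- manhattan[order(manhattan$chromosome, manhattan$locus_id,
                               manhattan$position), , drop = FALSE]

  res <- list(events = events, phase_counts = counts,
              selection = sel, selection_summary = sel_sum,
              gene_types = types, census = census, duration = dur,
              manhattan = manhattan, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) {
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "")
    }
    write_event_table(events, file.path(out_dir, "events.tsv"))
    w(counts, "phase_counts.tsv")
    if (!is.null(sel$rates)) {
      br <- do.call(rbind, lapply(
        sel$rates[c("phase1", "phase2_indica", "phase2_japonica")],
        function(b) data.frame(phase = b$phase, u = b$u,
                               total_mutations = b$total_mutations,
                               total_kb = b$total_kb,
                               n_introns = nrow(b$introns_used),
                               stringsAsFactors = FALSE)))
      w(br, "background_rates.tsv")
    }
    w(sel$calls, "selection_calls.tsv")
    w(sel_sum$table, "selection_summary.tsv")
    w(types$table, "gene_types.tsv")
    jsonlite::write_json(census, file.path(out_dir, "type_census.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    dur_json <- lapply(dur, function(d) {
      lapply(unclass(d), function(x) x)
    })
    jsonlite::write_json(dur_json, file.path(out_dir, "duration.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    w(manhattan, "manhattan.tsv")
    summary <- list(
      package_version = as.character(utils::packageVersion("ggmrice")),
      seed = dataset$manifest$seed %||% NA,
      config = config[setdiff(names(config), "u")],
      u_override = config$u %||% NA,
      config_hash = rlang::hash(config),
      n_loci = length(dataset$loci),
      n_events = nrow(events),
      n_selected_loci = if (nrow(sel_sum$counts) > 0L)
        stats::setNames(as.list(sel_sum$counts$n_union),
                        sel_sum$counts$phase) else list(),
      duration_status = vapply(dur, `[[`, "", "status"))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}
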