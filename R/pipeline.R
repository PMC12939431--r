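#' Run the full MA analysis pipeline on simulated data
#'
#' Orchestrates simulate -> call -> rates -> enrichment -> strand bias with
#' a single configuration and seed, writing every stage's output table and
#' a run manifest to `out_dir`.
#'
#' The configuration is a list (or a path to a JSON file) with optional
#' sections:
#' \describe{
#'   \item{seed}{integer master seed (default 1).}
#'   \item{out_dir}{output directory (default `"malines_run"`).}
#'   \item{sim}{arguments passed to [sim_config()] (except `seed`).}
#'   \item{caller}{arguments passed to [caller_params()].}
#'   \item{enrichment}{list with optional `tracks`: named character vector
#'     of BED paths to test in addition to the layout's centromeres.}
#'   \item{n_bins}{strand-bias profile bins (default 10).}
#'   \item{group}{cohort label (default `"MA"`).}
#' }
#' Unknown configuration keys raise an error naming the key.
#'
#' Outputs: `events.tsv`, `rates.tsv`, `enrichment.tsv`, `strandbias.tsv`,
#' `truth.tsv`, `origins.bed`, `manifest.json`.
#'
#' @param config list or JSON file path.
#' @return the run manifest (list), invisibly; element `paths` names all
#'   outputs.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  allowed <- c("seed", "out_dir", "sim", "caller", "enrichment", "n_bins",
               "group")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "malines_run" else config$out_dir
  group <- if (is.null(config$group)) "MA" else config$group
  n_bins <- if (is.null(config$n_bins)) 10L else as.integer(config$n_bins)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message(sprintf("[simulate] seed = %d", seed))

  cfg <- do.call(sim_config, c(list(seed = seed), config$sim))
  sim <- simulate_lineages(cfg)
  params <- do.call(caller_params, as.list(config$caller))

  message(sprintf("[call] %d isolates", cfg$isolates))
  events <- call_cohort_events(sim, params)

  message("[rates]")
  rates <- rate_table(events, s = cfg$isolates, n = cfg$passages,
                      generations = cfg$generations_per_passage,
                      group = group)

  message("[enrich]")
  tracks <- list(centromere = centromere_track(sim$layout))
  extra <- config$enrichment$tracks
  if (!is.null(extra))
    for (nm in names(extra))
      tracks[[nm]] <- read_bed_track(extra[[nm]], name = nm)
  enrich <- run_enrichment_panel(events, tracks, sim$layout, group = group)

  message("[strandbias]")
  variants <- do.call(rbind, lapply(sim$isolates, function(iso)
    filter_background(iso, sim$wt)$variants))
  muts <- a3b_mutations(variants, sim$origins)
  profile <- build_profile(muts, n_bins = n_bins)
  asym <- if (nrow(muts[muts$template != "ambiguous", ]))
    lagging_asymmetry(muts) else
    list(n = 0L, n_lagging = 0L, fraction = NA_real_, p = NA_real_)

  paths <- c(events = file.path(out_dir, "events.tsv"),
             rates = file.path(out_dir, "rates.tsv"),
             enrichment = file.path(out_dir, "enrichment.tsv"),
             strandbias = file.path(out_dir, "strandbias.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             origins = file.path(out_dir, "origins.bed"),
             manifest = file.path(out_dir, "manifest.json"))
  write_event_table(events, paths[["events"]])
  utils::write.table(rates, paths[["rates"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(enrich, paths[["enrichment"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(profile, paths[["strandbias"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed_track(element_track(sim$origins$chrom, sim$origins$pos - 1,
                                sim$origins$pos, name = "origin"),
                  paths[["origins"]])
  manifest <- list(
    package = "malines",
    version = as.character(utils::packageVersion("malines")),
    seed = seed, group = group,
    config = config[setdiff(names(config), "out_dir")],
    n_isolates = cfg$isolates, n_events = nrow(events),
    lagging_asymmetry = asym,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = as.list(unname(tools::md5sum(
      paths[setdiff(names(paths), "manifest")]))))
  names(manifest$outputs) <- setdiff(names(paths), "manifest")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest$paths <- paths
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Collects the stage outputs of [run_pipeline()] into report tables:
#' per-class rates, subtype composition per class, the enrichment panel and
#' the strand-bias profile. Missing stage files yield placeholder entries
#' instead of errors.
#'
#' @param out_dir the pipeline output directory.
#' @return list of class `MAReport` with elements `rates`, `composition`,
#'   `enrichment`, `strandbias`, `n_events`, `missing`.
#' @export
make_report <- function(out_dir) {
  read_or_null <- function(f)
    if (file.exists(f)) utils::read.table(f, sep = "\t", header = TRUE,
                                          stringsAsFactors = FALSE) else NULL
  events <- if (file.exists(file.path(out_dir, "events.tsv")))
    read_event_table(file.path(out_dir, "events.tsv")) else NULL
  missing <- character()
  composition <- NULL
  if (is.null(events)) {
    missing <- c(missing, "events.tsv")
  } else if (nrow(events)) {
    events$group <- "all"
    composition <- lapply(stats::setNames(nm = unique(events$class)),
                          function(cl) composition_table(events, cl))
  }
  rates <- read_or_null(file.path(out_dir, "rates.tsv"))
  if (is.null(rates)) missing <- c(missing, "rates.tsv")
  enrich <- read_or_null(file.path(out_dir, "enrichment.tsv"))
  if (is.null(enrich)) missing <- c(missing, "enrichment.tsv")
  sb <- read_or_null(file.path(out_dir, "strandbias.tsv"))
  if (is.null(sb)) missing <- c(missing, "strandbias.tsv")
  out <- list(rates = rates, composition = composition, enrichment = enrich,
              strandbias = sb,
              n_events = if (is.null(events)) 0L else nrow(events),
              missing = missing)
  class(out) <- "MAReport"
  out
}

#' @export
print.MAReport <- function(x, ...) {
  cat(sprintf("MA pipeline report: %d events\n", x$n_events))
  if (length(x$missing))
    cat("missing sections:", paste(x$missing, collapse = ", "), "\n")
  if (!is.null(x$rates)) {
    cat("\nPer-class rates:\n")
    print(x$rates, row.names = FALSE)
  }
  if (!is.null(x$enrichment)) {
    cat("\nEnrichment panel:\n")
    print(x$enrichment, row.names = FALSE)
  }
  invisible(x)
}
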