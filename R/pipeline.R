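#' Configuration for an end-to-end STORM overlap run
#'
#' @param out_dir output directory for all result files.
#' @param seed master integer seed (simulation mode); every source of
#'   randomness in the run derives from it.
#' @param conditions simulation mode: list of [sim_config()]s (e.g. from
#'   [condition_preset()]), one per condition. Ignored when `loc_files`
#'   is given.
#' @param loc_files real-data mode: named list mapping a ROI file (JSON,
#'   see [read_rois()]) to the localization CSVs it applies to:
#'   `list(list(roi_file=, loc_files=), ...)`. Each localization file is
#'   paired with the ROI of the same index.
#' @param precision_nm strict localization-precision threshold in nm;
#'   `NULL` disables the filter. Default 20.
#' @param pairs pairwise comparisons for [dunnett_t3()]; default all
#'   condition pairs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, conditions = NULL,
                            loc_files = NULL, precision_nm = 20,
                            pairs = NULL) {
  if (is.null(conditions) && is.null(loc_files))
    stop("either `conditions` (simulation) or `loc_files` (real data) ",
         "must be given", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 conditions = conditions, loc_files = loc_files,
                 precision_nm = precision_nm, pairs = pairs),
            class = "pipeline_config")
}

#' Run the STORM overlap pipeline end to end
#'
#' Simulation mode: generates each condition's ROIs to disk (localization
#' CSVs + ROI JSON), then reads them back through the same readers used
#' for real data — every stage consumes files, so each is independently
#' re-runnable. Each ROI is precision-filtered, subset to its region,
#' and scored ([analyze_roi()]); per-ROI results are aggregated by
#' condition and compared with [brown_forsythe_anova()] and
#' [dunnett_t3()]. No stage mutates its inputs. Outputs under `out_dir`:
#' `overlap_results.csv`, `condition_summaries.csv`, `anova.json`,
#' `pairwise.csv`, and `run_manifest.json` (config echo, package
#' version, seed). Output is byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with `results` (per-ROI data.frame),
#'   `groups`, `summaries`, `anova`, `pairwise`, and the output paths.
#' @export
run_storm_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  inputs <- if (!is.null(config$conditions)) {
    lapply(config$conditions, function(cc) {
      sim <- simulate_condition(cc, file.path(out, "sim", cc$condition))
      list(roi_file = sim$roi_file, loc_files = sim$loc_files)
    })
  } else config$loc_files

  results <- list()
  for (grp in inputs) {
    if (!file.exists(grp$roi_file))
      stop("ROI file not found: ", grp$roi_file, call. = FALSE)
    rois <- read_rois(grp$roi_file)
    if (length(rois) != length(grp$loc_files))
      stop("ROI count (", length(rois), ") and localization file count (",
           length(grp$loc_files), ") differ for ", grp$roi_file,
           call. = FALSE)
    for (i in seq_along(rois)) {
      roi <- rois[[i]]
      res <- tryCatch({
        tab <- read_localizations(grp$loc_files[[i]])
        if (!is.null(config$precision_nm))
          tab <- filter_by_precision(tab, config$precision_nm,
                                     quiet = quiet)
        analyze_roi(extract_roi(tab, roi), roi)$result
      }, error = function(e)
        stop("scoring stage failed for ROI ", roi$roi_id, ": ",
             conditionMessage(e), call. = FALSE))
      results[[length(results) + 1L]] <- res
    }
  }
  results <- do.call(rbind, results)
  utils::write.csv(results, file.path(out, "overlap_results.csv"),
                   row.names = FALSE)

  groups <- aggregate_conditions(results)
  summaries <- do.call(rbind, lapply(groups, function(g) {
    s <- summarize_scores(g$scores)
    data.frame(condition = g$label, n = s$n, mean = s$mean,
               variance = s$variance, median = s$median, q1 = s$q1,
               q3 = s$q3, stringsAsFactors = FALSE)
  }))
  utils::write.csv(summaries, file.path(out, "condition_summaries.csv"),
                   row.names = FALSE)

  anova <- pairwise <- NULL
  score_groups <- lapply(groups, `[[`, "scores")
  if (length(groups) >= 2L) {
    anova <- brown_forsythe_anova(score_groups)
    jsonlite::write_json(anova, file.path(out, "anova.json"),
                         auto_unbox = TRUE, digits = NA)
    pairwise <- dunnett_t3(score_groups, config$pairs)
    utils::write.csv(pairwise, file.path(out, "pairwise.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "smlmcoloc",
    version = as.character(utils::packageVersion("smlmcoloc")),
    seed = config$seed,
    precision_nm = config$precision_nm,
    mode = if (!is.null(config$conditions)) "simulate" else "real",
    conditions = if (!is.null(config$conditions))
      lapply(config$conditions, function(cc)
        list(condition = cc$condition, n_rois = cc$n_rois,
             seed = cc$seed))
    else lapply(inputs, `[[`, "roi_file")
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(results = results, groups = groups,
                 summaries = summaries, anova = anova,
                 pairwise = pairwise, out_dir = out))
}

#' Run the intensity-ratio pipeline
#'
#' Computes one [RatioResult][myoid_fraction] row per region per ratio
#' kind from a manifest of layered images, then compares the two groups
#' per ratio kind with the unpaired Student's t-test. Regions are given
#' in-memory as [layer_image()]s (synthetic or read via
#' [read_layer_image()]).
#'
#' @param regions list of lists `list(region_id=, group=, image=)` where
#'   `image` is a [layer_image()] whose masks include `IS`, `myoid`,
#'   `OS`, `ONL`; the first intensity channel is quantified.
#' @param out_dir output directory; `ratio_results.csv` and
#'   `ratio_tests.csv` are written there.
#' @return Invisibly, list with `ratios` (data.frame) and `tests`
#'   (data.frame, one row per ratio kind when exactly two groups are
#'   present).
#' @export
run_ratio_pipeline <- function(regions, out_dir) {
  if (length(regions) == 0L) stop("empty region manifest", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ratios <- do.call(rbind, lapply(regions, function(r) {
    img <- r$image$intensity[[1L]]
    m <- r$image$masks
    rbind(
      myoid_fraction(img, m$IS, m$myoid, r$region_id, r$group),
      is_photoreceptor_fraction(img, m[c("OS", "IS", "ONL")],
                                r$region_id, r$group)
    )
  }))
  utils::write.csv(ratios, file.path(out_dir, "ratio_results.csv"),
                   row.names = FALSE)

  tests <- NULL
  grps <- unique(ratios$group)
  if (length(grps) == 2L) {
    tests <- do.call(rbind, lapply(unique(ratios$kind), function(k) {
      a <- ratios$value[ratios$kind == k & ratios$group == grps[1L]]
      b <- ratios$value[ratios$kind == k & ratios$group == grps[2L]]
      tt <- student_t_unpaired(a, b)
      data.frame(kind = k, group_a = grps[1L], group_b = grps[2L],
                 mean_a = mean(a), mean_b = mean(b), t = tt$t,
                 df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }))
    utils::write.csv(tests, file.path(out_dir, "ratio_tests.csv"),
                     row.names = FALSE)
  }
  invisible(list(ratios = ratios, tests = tests))
}
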