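# Rebuild an assay_config with some fields overridden; special keys
# speed_multiplier / division_multiplier become an anonymous treatment.
modify_config <- function(config, overrides) {
  stopifnot(inherits(config, "assay_config"))
  args <- unclass(config)
  trs <- args$treatments
  sm <- overrides$speed_multiplier
  dm <- overrides$division_multiplier
  if (!is.null(sm) || !is.null(dm))
    trs <- c(trs, list(treatment("override", sm %||% 1, dm %||% 1)))
  overrides$speed_multiplier <- NULL
  overrides$division_multiplier <- NULL
  args[names(overrides)] <- overrides
  args$treatments <- trs
  do.call(assay_config, args)
}

#' Specification of an in-silico experiment
#'
#' A scenario is a set of arms (configuration overrides over a shared base),
#' a replicate count, and the metrics to read out per well. With
#' `paired_motility_seeds` every arm of a replicate shares the same
#' simulation seed, so seeding and the motility noise of the initial cohort
#' are identical across arms (see [run_assay()]).
#'
#' @param name Scenario label.
#' @param arms Named list; each element is a (possibly empty) list of
#'   [assay_config()] field overrides, plus optional `speed_multiplier` /
#'   `division_multiplier` treatment shortcuts.
#' @param replicates Replicates per arm.
#' @param outputs Metrics among `"dual"`, `"single"`, `"count_based"`,
#'   `"retention"`.
#' @param paired_motility_seeds Share per-replicate seeds across arms.
#' @param base_config Base [assay_config()].
#' @param geometry A [well_geometry()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, arms, replicates = 3L,
                          outputs = "dual", paired_motility_seeds = TRUE,
                          base_config = assay_config(),
                          geometry = well_geometry()) {
  stopifnot(is.list(arms), length(arms) >= 1L)
  if (is.null(names(arms)) || anyDuplicated(names(arms)))
    stop("scenario_spec: arms must be uniquely named")
  bad <- setdiff(outputs, c("dual", "single", "count_based", "retention"))
  if (length(bad))
    stop("scenario_spec: unsupported outputs: ", paste(bad, collapse = ", "),
         " (dye transfer experiments run through dye_transfer())")
  if (replicates < 1L) stop("scenario_spec: replicates must be >= 1")
  structure(list(name = name, arms = arms, replicates = as.integer(replicates),
                 outputs = outputs,
                 paired_motility_seeds = isTRUE(paired_motility_seeds),
                 base_config = base_config, geometry = geometry),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec '%s': %d arms x %d replicates (%s), metrics: %s\n",
              x$name, length(x$arms), x$replicates,
              if (x$paired_motility_seeds) "paired" else "independent",
              paste(x$outputs, collapse = ", ")))
  invisible(x)
}

#' Load a built-in scenario preset
#'
#' Presets live as YAML files under `extdata/scenarios/` and parameterize
#' the package's standard demonstrations: `"insensitivity"` (division off
#' vs on, paired, dye vs count readout), `"treatments"` (control /
#' actin-depolymerizer / cell-cycle-block / serum+ECM arms) and
#' `"dual_vs_single"` (four motility levels read out by both analysis
#' modes).
#'
#' @param name Preset name.
#' @param replicates Optional replicate-count override.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(name = c("insensitivity", "treatments",
                                     "dual_vs_single"),
                            replicates = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "zonemig", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  base <- do.call(assay_config, lapply(y$base_config %||% list(), unlist_scalar))
  geom <- do.call(well_geometry, c(y$geometry %||% list()))
  arms <- lapply(y$arms, function(a) lapply(a %||% list(), unlist_scalar))
  scenario_spec(y$name, arms, replicates %||% y$replicates,
                outputs = unlist(y$outputs),
                paired_motility_seeds = isTRUE(y$paired_motility_seeds),
                base_config = base, geometry = geom)
}

unlist_scalar <- function(x) if (is.list(x)) unlist(x) else x

# One rendered well quantified for the requested metrics. Returns a named
# numeric vector.
quantify_well <- function(sim, outputs, channels, render_seed) {
  geom <- sim$geometry
  set.seed(render_seed)
  vals <- c()
  need_t0v <- any(c("dual", "retention") %in% outputs)
  need_tfv <- any(c("dual", "single", "retention") %in% outputs)
  t0v <- if (need_t0v)
    render(sim$cells_t0, geom, channels$violet, timepoint = "t0")
  tfv <- if (need_tfv)
    render(sim$cells_tf, geom, channels$violet, timepoint = "tf")
  pair <- if ("dual" %in% outputs) detect_roi_pair(t0v)
  if ("dual" %in% outputs) {
    aligned <- align_roi_pair(pair, tfv)
    vals["dual"] <- relative_migration(tfv, aligned)$percent_migration
  }
  if ("single" %in% outputs) {
    std <- standard_roi_pair(geom)
    vals["single"] <- single_image_migration(tfv, std)$percent_migration
  }
  if ("count_based" %in% outputs) {
    t0n <- render(sim$cells_t0, geom, channels$nuclear, timepoint = "t0")
    tfn <- render(sim$cells_tf, geom, channels$nuclear, timepoint = "tf")
    cpair <- if (!is.null(pair)) align_roi_pair(pair, tfv %||% tfn)
             else translate_roi_pair(standard_roi_pair(geom),
                                     detect_well_roi(tfn)$center -
                                       standard_roi_pair(geom)$roi1$center)
    vals["count_based"] <- count_based_migration(
      tfn, cpair, t0_nuclear = t0n, method = "intensity")$percent_migration
  }
  if ("retention" %in% outputs) {
    ret <- dye_retention(list(t0v, tfv), c(0, sim$config$duration))
    vals["retention"] <- ret$percent_retained[2]
  }
  vals
}

#' Run a scenario
#'
#' Simulates every arm x replicate, renders the required synthetic
#' micrographs, quantifies the requested metrics, and returns a long-format
#' results table with per-row provenance. Deterministic for a given `seed`.
#'
#' @param spec A [scenario_spec()].
#' @param seed Master integer seed.
#' @param channels Named list of [channel_spec()]s (`violet`, `nuclear`).
#' @return A data.frame: `arm`, `replicate`, `metric`, `value`, `seed`,
#'   `config_hash`.
#' @export
run_scenario <- function(spec, seed = 1L,
                         channels = list(violet = channel_spec("violet"),
                                         nuclear = channel_spec("nuclear"))) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  n_arms <- length(spec$arms)
  R <- spec$replicates
  sim_seeds <- matrix(sample.int(2147483646L, n_arms * R,
                                 replace = FALSE), nrow = R)
  if (spec$paired_motility_seeds)
    sim_seeds <- matrix(rep(sim_seeds[, 1L], n_arms), nrow = R)
  render_seeds <- matrix(sample.int(2147483646L, n_arms * R), nrow = R)
  rows <- list()
  for (a in seq_len(n_arms)) {
    arm <- names(spec$arms)[a]
    cfg_arm <- modify_config(spec$base_config, spec$arms[[a]])
    hash <- config_hash(cfg_arm)
    for (r in seq_len(R)) {
      cfg <- cfg_arm
      cfg$rng_seed <- sim_seeds[r, a]
      sim <- run_assay(cfg, spec$geometry)
      vals <- quantify_well(sim, spec$outputs, channels, render_seeds[r, a])
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, replicate = r, metric = names(vals), value = unname(vals),
        seed = sim_seeds[r, a], config_hash = hash)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Stable short hash of a configuration (polynomial rolling hash over its
# deparsed form; all arithmetic stays below 2^53 so doubles are exact).
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Compare scenario arms by ANOVA with post hoc tests
#'
#' Standard one- or two-way analysis of variance on a long results table,
#' followed by Tukey all-pairs or Dunnett many-to-one adjusted comparisons —
#' the conventional statistical treatment of multi-arm migration
#' experiments, with significance declared at `alpha`.
#'
#' @param table Data.frame with a numeric `value` column and the factor
#'   columns named in `factors`.
#' @param design `"one_way"` (first factor only) or `"two_way"` (both
#'   factors plus their interaction).
#' @param factors Character vector of one or two factor column names.
#' @param posthoc `"tukey"` or `"dunnett"`.
#' @param control Control level for Dunnett (default: first level).
#' @param alpha Significance level.
#' @return An object of class `group_comparison`: `design`, `omnibus_p`
#'   (named per model term), `posthoc` (data.frame with adjusted and
#'   unadjusted p-values for Tukey; adjusted for Dunnett), `alpha`, `fit`.
#' @export
compare_groups <- function(table, design = c("one_way", "two_way"),
                           factors = "arm", posthoc = c("tukey", "dunnett"),
                           control = NULL, alpha = 0.05) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  stopifnot(is.data.frame(table), "value" %in% names(table),
            all(factors %in% names(table)))
  if (design == "two_way" && length(factors) != 2L)
    stop("compare_groups: two_way design needs two factor columns")
  df <- table
  for (f in factors) df[[f]] <- factor(df[[f]])
  if (!is.null(control))
    df[[factors[1]]] <- stats::relevel(df[[factors[1]]], ref = control)
  fml <- if (design == "one_way")
    stats::reformulate(factors[1], response = "value")
  else
    stats::as.formula(paste("value ~", factors[1], "*", factors[2]))
  fit <- stats::aov(fml, data = df)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  omnibus_p <- stats::setNames(an[["Pr(>F)"]], terms)
  omnibus_p <- omnibus_p[!is.na(omnibus_p)]

  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit, which = factors[1])[[factors[1]]]
    ph <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adjusted = tk[, "p adj"], row.names = NULL)
    # unadjusted pairwise p for the adjustment-monotonicity check
    pw <- stats::pairwise.t.test(df$value, df[[factors[1]]],
                                 p.adjust.method = "none")$p.value
    unadj <- stats::setNames(
      as.vector(pw),
      as.vector(outer(rownames(pw), colnames(pw),
                      function(a, b) paste0(a, "-", b))))
    unadj <- unadj[!is.na(unadj)]
    key2 <- sub("^(.*)-(.*)$", "\\2-\\1", names(unadj))
    ph$p_unadjusted <- unadj[match(ph$comparison, names(unadj))]
    miss <- is.na(ph$p_unadjusted)
    ph$p_unadjusted[miss] <- unadj[match(ph$comparison[miss], key2)]
  } else {
    gl <- multcomp::glht(fit, linfct = do.call(
      multcomp::mcp, stats::setNames(list("Dunnett"), factors[1])))
    sm <- summary(gl)
    ph <- data.frame(comparison = names(sm$test$coefficients),
                     diff = unname(sm$test$coefficients),
                     p_adjusted = unname(sm$test$pvalues), row.names = NULL)
  }
  structure(list(design = design, omnibus_p = omnibus_p, posthoc = ph,
                 alpha = alpha, fit = fit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s ANOVA), alpha = %g\n", x$design, x$alpha))
  cat("omnibus p:\n"); print(round(x$omnibus_p, 4))
  cat("post hoc:\n"); print(x$posthoc, digits = 4)
  invisible(x)
}

#' Write scenario results, summary, figure and manifest
#'
#' Produces `results.csv` (the long table), `summary.csv` (mean, SD, SEM, n
#' per arm x metric), a bar chart of arm means with SEM error bars
#' (`figure.pdf`), and `manifest.json` recording the scenario, seeds and
#' session versions. CSV outputs are byte-identical across reruns with the
#' same inputs.
#'
#' @param results Long table from [run_scenario()].
#' @param comparisons Optional [compare_groups()] result (or named list of
#'   them) serialized into the manifest.
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
report <- function(results, comparisons = NULL, out_dir) {
  if (!is.data.frame(results) || !nrow(results))
    stop("report: empty results table")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f_results <- file.path(out_dir, "results.csv")
  utils::write.csv(results, f_results, row.names = FALSE)

  agg <- do.call(rbind, lapply(
    split(results, list(results$arm, results$metric), drop = TRUE),
    function(d) data.frame(arm = d$arm[1], metric = d$metric[1],
                           n = nrow(d), mean = mean(d$value),
                           sd = stats::sd(d$value),
                           sem = stats::sd(d$value) / sqrt(nrow(d)))))
  agg <- agg[order(agg$metric, agg$arm), ]
  rownames(agg) <- NULL
  f_summary <- file.path(out_dir, "summary.csv")
  utils::write.csv(agg, f_summary, row.names = FALSE)

  f_fig <- file.path(out_dir, "figure.pdf")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = arm, y = mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                           width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative migration (%)") +
    ggplot2::theme_classic()
  ggplot2::ggsave(f_fig, p, width = 2 + 1.2 * length(unique(agg$arm)),
                  height = 3.5, units = "in")

  f_manifest <- file.path(out_dir, "manifest.json")
  manifest <- list(
    arms = as.list(sort(unique(results$arm))),
    metrics = as.list(sort(unique(results$metric))),
    replicates = max(results$replicate),
    seeds = sort(unique(results$seed)),
    config_hashes = as.list(sort(unique(results$config_hash))),
    comparisons = if (!is.null(comparisons)) {
      cl <- if (inherits(comparisons, "group_comparison"))
        list(comparisons) else comparisons
      lapply(cl, function(cc) list(design = cc$design,
                                   omnibus_p = as.list(cc$omnibus_p)))
    },
    zonemig_version = as.character(utils::packageVersion("zonemig")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(f_results, f_summary, f_fig, f_manifest))
}
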