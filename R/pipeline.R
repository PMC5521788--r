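#' Assemble a pipeline configuration
#'
#' Validates and normalises the configuration driving [run_pipeline()].
#' A configuration names one or more experimental conditions, each with
#' a clonogenic dataset (CSV path or data frame with columns
#' `dose_Gy` *or* `activity_MBq`, plus `colonies`, `seeded`,
#' `replicate`), the survival model to fit, and - for activity-based
#' conditions - the decay chain and S-value tables that convert applied
#' activity into absorbed dose (medium route, optionally plus a
#' specific-binding route via `bound_activity_per_MBq`, the bound
#' activity per cell at the end of incubation per MBq applied).
#'
#' @param conditions Named list; each element a list with fields
#'   `data`, `model` (`"LQ"`/`"linear"`), and optionally `chain`
#'   (`"bi213"`, `"lu177"` or a CSV path), `bound_activity_per_MBq`,
#'   `f_int`, `f_mem`.
#' @param reference Name of the reference condition for RBE (exactly
#'   one, must be a condition name).
#' @param layer_s_values,cell_s_values CSV paths; defaults are the
#'   packaged tables.
#' @param incubation_s Incubation window, seconds.
#' @param cell_window_s Specific-binding integration window, seconds.
#' @param survival_levels Survival levels for dose readout (default
#'   D10 and D20).
#' @param dose_floor_Gy Conditions whose maximum absorbed dose falls
#'   below this are flagged sub-threshold and their D10/D20 readout is
#'   suppressed.
#' @param out_dir Optional output directory for JSON + TSV reports.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions,
                            reference,
                            layer_s_values = NULL,
                            cell_s_values = NULL,
                            incubation_s = c(0, 3600),
                            cell_window_s = c(3600, 12 * 86400),
                            survival_levels = c(0.1, 0.2),
                            dose_floor_Gy = 1e-3,
                            out_dir = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be a named list", call. = FALSE)
  }
  if (length(reference) != 1L || !reference %in% names(conditions)) {
    stop("reference must name exactly one configured condition",
         call. = FALSE)
  }
  layer <- if (is.null(layer_s_values)) layer_s_values_bi213()
           else read_layer_s_values(layer_s_values)
  cells <- if (is.null(cell_s_values)) cell_s_values_6um()
           else read_cell_s_values(cell_s_values)
  structure(
    list(conditions = conditions, reference = reference,
         layer_s_values = layer, cell_s_values = cells,
         incubation_s = incubation_s, cell_window_s = cell_window_s,
         survival_levels = survival_levels,
         dose_floor_Gy = dose_floor_Gy, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' YAML mirror of [pipeline_config()]; condition `data` entries are
#' CSV paths resolved relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  conds <- lapply(y$conditions, function(cd) {
    if (is.character(cd$data)) cd$data <- resolve(cd$data)
    if (!is.null(cd$chain) && !cd$chain %in% c("bi213", "lu177")) {
      cd$chain <- resolve(cd$chain)
    }
    cd
  })
  pipeline_config(
    conditions = conds,
    reference = y$reference,
    layer_s_values = resolve(y$layer_s_values),
    cell_s_values = resolve(y$cell_s_values),
    incubation_s = y$incubation_s %||% c(0, 3600),
    cell_window_s = y$cell_window_s %||% c(3600, 12 * 86400),
    survival_levels = y$survival_levels %||% c(0.1, 0.2),
    dose_floor_Gy = y$dose_floor_Gy %||% 1e-3,
    out_dir = y$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_chain <- function(spec) {
  if (is.null(spec)) return(NULL)
  switch(spec,
         bi213 = bi213_chain(),
         lu177 = lu177_chain(),
         read_chain(spec))
}

load_clonogenic <- function(data) {
  df <- if (is.character(data)) utils::read.csv(data) else as.data.frame(data)
  if (nrow(df) == 0L) stop("empty clonogenic dataset", call. = FALSE)
  if (!all(c("colonies", "seeded") %in% names(df))) {
    stop("clonogenic data needs columns colonies, seeded", call. = FALSE)
  }
  if (!("dose_Gy" %in% names(df)) && !("activity_MBq" %in% names(df))) {
    stop("clonogenic data needs a dose_Gy or activity_MBq column",
         call. = FALSE)
  }
  df
}

#' Run the full dose-survival-RBE pipeline
#'
#' For every configured condition: converts applied activity to
#' absorbed dose where needed (medium dose to the bottom cell layer
#' plus, when configured, specific-binding cellular dose, with the
#' percentage split between routes reported), estimates the plating
#' efficiency from 0-dose control wells, computes surviving fractions,
#' fits the configured survival model, reads out the dose at the
#' configured survival levels (suppressed with a `sub_threshold` flag
#' when the achievable dose range cannot support it), and tabulates RBE
#' against the reference condition at each survival level. The run is
#' deterministic: the report is a pure function of the configuration
#' and input files.
#'
#' @param cfg A `pipeline_config` (or YAML path).
#' @return List of class `pipeline_report` with elements `conditions`
#'   (per-condition results), `rbe` (data frame), `reference`. When
#'   `cfg$out_dir` is set, writes `report.json` and `rbe.tsv` there.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))

  results <- lapply(names(cfg$conditions), function(nm) {
    cd <- cfg$conditions[[nm]]
    df <- load_clonogenic(cd$data)
    model <- cd$model %||% "LQ"

    if ("dose_Gy" %in% names(df)) {
      df$dose_total_Gy <- df$dose_Gy
      dose_split <- data.frame(route = "direct", percent = 100)
    } else {
      chain <- resolve_chain(cd$chain)
      if (is.null(chain)) {
        stop("condition '", nm, "' has activity_MBq but no chain for ",
             "dose conversion", call. = FALSE)
      }
      med_per_MBq <- medium_dose(1, chain, cfg$incubation_s,
                                 cfg$layer_s_values)$total_Gy
      spec_per_MBq <- 0
      if (!is.null(cd$bound_activity_per_MBq)) {
        spec_per_MBq <- cell_mean_dose(
          cd$bound_activity_per_MBq, chain,
          f_int = cd$f_int %||% 0, f_mem = cd$f_mem %||% 1,
          svals = cfg$cell_s_values, window = cfg$cell_window_s
        )$total_Gy
      }
      per_MBq <- med_per_MBq + spec_per_MBq
      df$dose_total_Gy <- df$activity_MBq * per_MBq
      dose_split <- data.frame(
        route = c("medium", "specific"),
        percent = if (per_MBq > 0)
          100 * c(med_per_MBq, spec_per_MBq) / per_MBq else c(0, 0)
      )
    }

    ctrl <- df[df$dose_total_Gy == 0, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop("condition '", nm, "' has no 0-dose control wells for plating ",
           "efficiency", call. = FALSE)
    }
    pe <- sum(ctrl$colonies) / sum(ctrl$seeded)
    trt <- df[df$dose_total_Gy > 0, , drop = FALSE]
    sf <- surviving_fraction(trt$colonies, trt$seeded, pe)

    max_dose <- max(df$dose_total_Gy)
    sub_threshold <- max_dose < cfg$dose_floor_Gy
    fit <- NULL; doses_at <- rep(NA_real_, length(cfg$survival_levels))
    abr <- NULL
    if (!sub_threshold) {
      fit <- fit_survival_counts(df$dose_total_Gy, df$colonies, df$seeded,
                                 model)
      doses_at <- vapply(cfg$survival_levels,
                         function(s) dose_at_survival(fit, s), 0)
      if (model == "LQ") abr <- alpha_beta_ratio(fit)
    }
    list(name = nm, plating_efficiency = pe, dose_split = dose_split,
         max_dose_Gy = max_dose, sub_threshold = sub_threshold,
         fit = fit, survival_levels = cfg$survival_levels,
         dose_at_levels_Gy = doses_at, alpha_beta = abr)
  })
  names(results) <- names(cfg$conditions)

  ref <- results[[cfg$reference]]
  rbe_tab <- do.call(rbind, lapply(results, function(res) {
    data.frame(
      condition = res$name,
      survival_level = cfg$survival_levels,
      dose_Gy = res$dose_at_levels_Gy,
      rbe = ifelse(
        is.na(res$dose_at_levels_Gy) | is.na(ref$dose_at_levels_Gy),
        NA_real_, ref$dose_at_levels_Gy / res$dose_at_levels_Gy)
    )
  }))
  rownames(rbe_tab) <- NULL

  report <- structure(
    list(conditions = results, rbe = rbe_tab, reference = cfg$reference),
    class = "pipeline_report"
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_as_list(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(rbe_tab, file.path(cfg$out_dir, "rbe.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

report_as_list <- function(report) {
  conds <- lapply(report$conditions, function(res) {
    fit <- res$fit
    list(
      plating_efficiency = res$plating_efficiency,
      dose_split_percent = stats::setNames(as.list(res$dose_split$percent),
                                           res$dose_split$route),
      max_dose_Gy = res$max_dose_Gy,
      sub_threshold = res$sub_threshold,
      model = if (!is.null(fit)) fit$model else NULL,
      alpha = if (!is.null(fit)) fit$alpha else NULL,
      alpha_se = if (!is.null(fit)) fit$alpha_se else NULL,
      beta = if (!is.null(fit)) fit$beta else NULL,
      beta_se = if (!is.null(fit)) fit$beta_se else NULL,
      r_squared = if (!is.null(fit)) fit$r_squared else NULL,
      alpha_at_bound = if (!is.null(fit)) fit$alpha_at_bound else NULL,
      alpha_beta_ratio = if (!is.null(res$alpha_beta))
        res$alpha_beta$ratio else NULL,
      dose_at_levels_Gy = stats::setNames(
        as.list(res$dose_at_levels_Gy),
        paste0("S", res$survival_levels * 100))
    )
  })
  list(reference = report$reference, conditions = conds,
       rbe = report$rbe)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d condition(s), reference: %s\n",
              length(x$conditions), x$reference))
  for (res in x$conditions) {
    cat(sprintf("- %s: PE %.3f, max dose %.3g Gy%s", res$name,
                res$plating_efficiency, res$max_dose_Gy,
                if (res$sub_threshold) " [sub-threshold]" else ""))
    if (!is.null(res$fit)) {
      cat(sprintf(", %s alpha %.3g", res$fit$model, res$fit$alpha))
      if (res$fit$model == "LQ") cat(sprintf(" beta %.3g", res$fit$beta))
    }
    cat("\n")
  }
  cat("RBE table:\n")
  print(transform(x$rbe, dose_Gy = signif(dose_Gy, 4),
                  rbe = signif(rbe, 3)))
  invisible(x)
}
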