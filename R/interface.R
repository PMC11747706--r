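# Dataset dialect, validated I/O and the pipeline orchestrator.
#
# The CSV dialect is the field-standard event encoding: one row per dose or
# observation event. Columns:
#   ID    subject identifier
#   TIME  event time (h), non-decreasing within subject
#   AMT   dose per administration (mg); dose rows only
#   II    inter-dose interval (h); dose rows only (steady-state dosing)
#   DV    observed concentration (ng/mL); observation rows only
#   MDV   1 = dose row (DV missing), 0 = observation row
#   WT    body weight (kg)
#   ZOP   zopiclone co-administration flag (0/1), optional
# plus any extra covariate columns, carried through unmodeled.

TDM_REQUIRED <- c("ID", "TIME", "AMT", "II", "DV", "MDV", "WT")

#' Validate a data frame as a TDM event dataset
#'
#' Checks the dialect contract and reports every violation with its row
#' number; nothing is loaded partially. Used by [read_tdm()] and by the
#' simulators before handing a dataset to estimation.
#'
#' @param df data frame in the event dialect described under [read_tdm()].
#' @return The validated data frame with class `tdm_dataset`.
#' @export
as_tdm_dataset <- function(df) {
  if (!is.data.frame(df)) stop_bad("expected a data frame")
  miss <- setdiff(TDM_REQUIRED, names(df))
  if (length(miss)) {
    stop_bad("missing mandatory columns: ", paste(miss, collapse = ", "))
  }
  probs <- character()
  note <- function(rows, msg) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<-
        paste0(msg, " (row ", paste(rows, collapse = ", "), ")")
    }
  }
  for (cc in c("TIME", "AMT", "II", "DV", "MDV", "WT")) {
    if (!is.numeric(df[[cc]]) && !all(is.na(df[[cc]]))) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))) &
                     !is.na(df[[cc]]))
      note(bad, paste0("non-numeric ", cc))
      df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    } else {
      df[[cc]] <- as.numeric(df[[cc]])
    }
  }
  note(which(!df$MDV %in% c(0, 1)), "MDV must be 0 or 1")
  note(which(!is.finite(df$TIME) | df$TIME < 0), "TIME must be finite and >= 0")
  note(which(!is.finite(df$WT) | df$WT <= 0), "WT must be positive")
  dose <- df$MDV == 1
  obs <- df$MDV == 0
  note(which(dose & (!is.finite(df$AMT) | df$AMT < 0)),
       "dose row needs AMT >= 0")
  note(which(dose & (!is.finite(df$II) | df$II <= 0)),
       "dose row needs II > 0")
  note(which(dose & !is.na(df$DV)), "DV present on an MDV=1 row")
  note(which(obs & !is.finite(df$DV)), "observation row needs a finite DV")
  note(which(obs & !is.na(df$AMT) & df$AMT != 0),
       "AMT present on an observation row")
  if ("ZOP" %in% names(df)) {
    note(which(!df$ZOP %in% c(0, 1)), "ZOP must be 0 or 1")
  }
  for (id in unique(df$ID)) {
    rows <- which(df$ID == id)
    tt <- df$TIME[rows]
    bad <- rows[which(diff(tt) < 0) + 1L]
    note(bad, paste0("TIME not non-decreasing within subject ", id))
    orow <- rows[df$MDV[rows] == 0]
    drow <- rows[df$MDV[rows] == 1]
    if (length(orow)) {
      if (!length(drow)) {
        note(orow, paste0("subject ", id, " has observations but no dose row"))
      } else {
        nodose <- orow[vapply(orow, function(r) {
          !any(df$TIME[drow] <= df$TIME[r])
        }, TRUE)]
        note(nodose, paste0("observation before any dose for subject ", id))
      }
    }
  }
  if (length(probs)) {
    stop_bad("invalid TDM dataset:\n  ", paste(probs, collapse = "\n  "))
  }
  class(df) <- c("tdm_dataset", "data.frame")
  df
}

#' Read / write TDM event datasets
#'
#' `read_tdm()` reads a CSV in the event dialect (see [as_tdm_dataset()]
#' for the column contract) and validates it fully before returning;
#' `write_tdm()` writes a dataset back out so that reading it again
#' reproduces the data exactly.
#'
#' @param path CSV file path.
#' @param x a `tdm_dataset` (or conforming data frame) to write.
#' @return `read_tdm` returns a `tdm_dataset`; `write_tdm` returns `path`
#'   invisibly.
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  as_tdm_dataset(df)
}

#' @rdname read_tdm
#' @export
write_tdm <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- pipeline ------------------------------------------------------------

default_stages <- c("simulate", "fit", "covstep", "bootstrap", "vpc", "gof",
                    "pta", "recommend")

resolve_model <- function(x) {
  if (is.null(x) || identical(x, "final")) return(sertraline_final_model())
  if (inherits(x, "pop_model")) return(x)
  if (is.character(x)) return(read_model_config(x))
  model_from_list(x)
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates cohort simulation, mixed-effects fitting, bootstrap, VPC,
#' goodness-of-fit tables, the probability-of-target-attainment grid and
#' the dose recommendation, writing every artifact as headed CSV (plus a
#' JSON fit report) into `out_dir` together with a run manifest recording
#' seeds, stage status and every interpretation/design flag.
#'
#' The configuration is a named list (or a YAML/JSON file holding one):
#'
#' * `seed`: master seed; per-stage seeds are derived from it.
#' * `model`: `"final"` (default), a [pop_model()], a config-file path or a
#'   flat list as written by [write_model_config()].
#' * `stages`: subset of `simulate`, `fit`, `covstep`, `bootstrap`, `vpc`,
#'   `gof`, `pta`, `recommend` (default all). Stages depending on a skipped
#'   or failed stage are skipped; upstream outputs are preserved.
#' * `covstep`: `candidates` (list of [covariate_candidate()] argument
#'   lists) plus optional `add_threshold` / `remove_threshold`; with no
#'   candidates the stage just records the base-model trace.
#' * `dataset`: path to an existing dataset (alternative to `simulate`).
#' * `cohort`: arguments for [cohort_spec()].
#' * `fit`: arguments for [fit_spec()].
#' * `bootstrap`: `n_boot` (default 200).
#' * `vpc`: `n_rep` (default 200), `bins` (default 6).
#' * `pta`: `scenarios` (list of [pta_scenario()] argument lists; default
#'   the four published once/twice-daily x zopiclone scenarios) and
#'   `n_virtual` (default 1000).
#' * `recommend`: `bands` (default the published 30--38.5 / 38.5--80 kg
#'   split once daily without zopiclone, 30--80 otherwise) and `statistic`.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the in-memory artifacts and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% default_stages
  bad <- setdiff(stages, default_stages)
  if (length(bad)) stop_bad("unknown stages: ", paste(bad, collapse = ", "))
  model <- resolve_model(config$model)

  state <- list(model = model)
  manifest <- list(seed = seed, stages = stages,
                   package_version = as.character(utils::packageVersion("sertmipd")),
                   omega_mode = model$omega_mode, sigma_mode = model$sigma_mode,
                   stage_status = list(), stage_seconds = list())
  failed <- FALSE
  needs <- list(fit = "dataset", covstep = "dataset", bootstrap = "fit",
                vpc = "dataset", gof = "fit", recommend = "pta")

  if (!is.null(config$dataset)) {
    state$dataset <- read_tdm(config$dataset)
  }

  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stage_status[[name]] <<- "skipped (upstream failure)"
      return(invisible())
    }
    dep <- needs[[name]]
    if (!is.null(dep) && is.null(state[[dep]])) {
      manifest$stage_status[[name]] <<- paste0("skipped (needs ", dep, ")")
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    manifest$stage_seconds[[name]] <<-
      round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      manifest$stage_status[[name]] <<- paste0("error: ", conditionMessage(res))
      failed <<- TRUE
    } else {
      manifest$stage_status[[name]] <<- "ok"
    }
    invisible()
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    ca <- config$cohort %||% list()
    ca$seed <- ca$seed %||% derive_seed(seed, 1L)
    spec <- do.call(cohort_spec, ca)
    cohort <- generate_cohort(spec)
    state$dataset <<- simulate_tdm(cohort, model,
                                   troughs_per_subject = spec$troughs_per_subject,
                                   visit_days = spec$visit_days,
                                   seed = derive_seed(seed, 2L))
    write_tdm(state$dataset, file.path(out_dir, "dataset.csv"))
  })

  if ("fit" %in% stages) run_stage("fit", function() {
    fa <- config$fit %||% list()
    spec <- do.call(fit_spec, fa)
    state$fit <<- fit_ppk(state$dataset, model, spec)
    utils::write.csv(fit_table(state$fit),
                     file.path(out_dir, "fit_parameters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fit_report(state$fit),
                         file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  if ("covstep" %in% stages) run_stage("covstep", function() {
    cc <- config$covstep %||% list()
    cands <- lapply(cc$candidates %||% list(), function(cd) {
      covariate_candidate(cd$name, cd$parameter %||% "cl",
                          cd$kind %||% "linear")
    })
    res <- stepwise_covariates(state$dataset, model, cands,
                               add_threshold = cc$add_threshold %||% 3.84,
                               remove_threshold = cc$remove_threshold %||% 6.63,
                               spec = do.call(fit_spec, config$fit %||% list()))
    state$covstep <<- res
    utils::write.csv(res$trace, file.path(out_dir, "covstep_trace.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(res)),
               file.path(out_dir, "covstep.log"))
  })

  if ("bootstrap" %in% stages) run_stage("bootstrap", function() {
    n_boot <- config$bootstrap$n_boot %||% 200L
    bs <- bootstrap_ppk(state$dataset, state$fit, n_boot = n_boot,
                        seed = derive_seed(seed, 3L))
    state$bootstrap <<- bs
    utils::write.csv(bs, file.path(out_dir, "bootstrap.csv"),
                     row.names = FALSE)
  })

  if ("vpc" %in% stages) run_stage("vpc", function() {
    mv <- if (!is.null(state$fit)) state$fit$model else model
    vp <- vpc_ppk(state$dataset, mv,
                  n_rep = config$vpc$n_rep %||% 200L,
                  bins = config$vpc$bins %||% 6L,
                  seed = derive_seed(seed, 4L))
    state$vpc <<- vp
    utils::write.csv(vp, file.path(out_dir, "vpc.csv"), row.names = FALSE)
  })

  if ("gof" %in% stages) run_stage("gof", function() {
    gt <- gof_table(state$dataset, state$fit$model, state$fit)
    state$gof <<- gt
    utils::write.csv(gt, file.path(out_dir, "gof.csv"), row.names = FALSE)
  })

  if ("pta" %in% stages) run_stage("pta", function() {
    mv <- if (!is.null(state$fit)) state$fit$model else model
    scen_args <- config$pta$scenarios %||% list(
      list(zop = 0, interval = 24), list(zop = 0, interval = 12),
      list(zop = 1, interval = 24), list(zop = 1, interval = 12))
    n_virtual <- config$pta$n_virtual %||% 1000L
    tabs <- lapply(seq_along(scen_args), function(i) {
      sa <- scen_args[[i]]
      sa$n_virtual <- sa$n_virtual %||% n_virtual
      sa$seed <- sa$seed %||% derive_seed(seed, 10L + i)
      pta_grid(mv, do.call(pta_scenario, sa))
    })
    state$pta <<- do.call(rbind, tabs)
    utils::write.csv(state$pta, file.path(out_dir, "pta.csv"),
                     row.names = FALSE)
  })

  if ("recommend" %in% stages) run_stage("recommend", function() {
    stat <- config$recommend$statistic %||% "mean"
    bands <- config$recommend$bands
    recs <- lapply(split(state$pta,
                         list(state$pta$zop, state$pta$interval),
                         drop = TRUE),
                   function(tab) {
      b <- bands %||% (if (tab$zop[1] == 0 && tab$interval[1] == 24)
        list(c(30, 38.5), c(38.5, 80)) else list(c(30, 80)))
      if (is.matrix(b)) b <- asplit(b, 1)
      recommend_dose(tab, bands = b, statistic = stat)
    })
    state$recommendation <<- do.call(rbind, c(recs, make.row.names = FALSE))
    utils::write.csv(state$recommendation,
                     file.path(out_dir, "recommendations.csv"),
                     row.names = FALSE)
  })

  manifest$completed <- !failed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(state, list(manifest = manifest)))
}
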