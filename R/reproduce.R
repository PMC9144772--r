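#' Structured log event
#'
#' Emits a single JSON-lines record to stderr (and, when the option
#' `uaeopt.log_file` is set, appends it there). Logging never alters
#' any numerical result.
#'
#' @param level One of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @param message_text Human-readable message.
#' @param context Named list of additional fields (must survive a JSON
#'   round trip).
#' @return The record, invisibly.
#' @export
log_event <- function(level = c("info", "debug", "warning", "error"),
                      message_text, context = list()) {
  level <- match.arg(level)
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                level = level, message = message_text), context)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  message(line)
  log_file <- getOption("uaeopt.log_file", NULL)
  if (!is.null(log_file)) cat(line, "\n", sep = "", file = log_file, append = TRUE)
  invisible(rec)
}

#' Re-run the full published analysis against its printed results
#'
#' Runs every stage of the pipeline on the packaged fixtures and checks
#' each recomputed quantity against the corresponding printed value at a
#' stored tolerance: the composite column of the 30-run design; the
#' refit quadratic coefficients; the ANOVA fit statistics (R2, adjusted
#' and predicted R2, model F, lack-of-fit F); the mean squared error
#' between the published LS-SVM predictions and the replicate-averaged
#' actuals; the constrained maximum of the quadratic surface; and the
#' two validation-experiment summaries with their relative deviations.
#'
#' Tolerances: 5e-5 for pure-arithmetic reproductions (composite column,
#' tabulated-prediction MSE, printed means), 0.002 for refit R2-type
#' statistics, 0.005 for coefficients printed at two decimals, 0.02 for
#' the surface optimum, 0.5 for the model F, 0.02 for the lack-of-fit F
#' and 0.01 for relative deviations — sized to absorb the source's
#' printed rounding, nothing more.
#'
#' @param weights A `weight_scheme` for the composite (the published
#'   0.75/0.25 by default; changing it demonstrates the sensitivity of
#'   every downstream check).
#' @param out_dir Optional directory: the report is written there as
#'   `reproduction.json` plus the recomputed ANOVA as
#'   `anova_table.csv`.
#' @param verbose Emit one [log_event()] per pipeline stage.
#' @return A `reproduction_report`: data.frame `checks` (check, value,
#'   target, tol, pass) with attribute `all_pass`.
#' @export
reproduce_paper <- function(weights = fixture_weights(), out_dir = NULL,
                            verbose = TRUE) {
  say <- function(msg, ...) if (verbose) log_event("info", msg, list(...))
  checks <- list()
  add <- function(check, value, target, tol) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, value = as.numeric(value), target = as.numeric(target),
      tol = tol, pass = is.finite(value) && abs(value - target) <= tol,
      stringsAsFactors = FALSE)
  }

  say("loading fixtures")
  tab2 <- load_fixture("table2")
  tab4 <- load_fixture("table4")
  tab5 <- load_fixture("table5")

  say("stage 1: composite scoring")
  rescored <- add_composite(tab2, weights)
  add("composite_max_abs_diff",  # 1e-12 absorbs float representation of the half-ulp
      max(abs(rescored$Y - tab2$Y)), 0, 5e-5 + 1e-12)
  add("composite_min", min(rescored$Y), 11.4212, 5e-5)
  add("composite_max", max(rescored$Y), 13.1058, 5e-5)

  say("stage 2: quadratic response-surface refit")
  model <- fit_quadratic(tab2)
  b <- coef(model)
  eq2 <- c(`(Intercept)` = 13.01, time = 0.17, temperature = 0.055,
           ratio = 0.11, ethanol = -0.28)
  for (term in names(eq2))
    add(paste0("coef_", term), b[[term]], eq2[[term]], 0.005)

  say("stage 3: ANOVA")
  an <- anova_quadratic(model)
  add("r2", an$r2, 0.9913, 0.002)
  add("adj_r2", an$adj_r2, 0.9832, 0.002)
  add("pred_r2", an$pred_r2, 0.9641, 0.002)
  add("model_f", an$table$f[an$table$source == "Model"], 121.9277, 0.5)
  add("lack_of_fit_f", an$lack_of_fit$f, 0.82, 0.02)

  say("stage 4: LS-SVM arithmetic (published predictions vs averaged actuals)")
  avg <- aggregate_replicates(tab2)
  add("lssvm_published_mse", mse(tab4$predicted, avg$Y), 0.1357, 5e-5)

  say("stage 5: surface optimization")
  opt <- maximize_quadratic(model)
  add("rsm_optimum", opt$value, 13.0870, 0.02)

  say("stage 6: validation comparison")
  reports <- lapply(split(tab5, tab5$method), function(d)
    validation_report(d, predicted = d$predicted[1L], weights = weights,
                      label = d$method[1L]))
  add("validation_mean_rsm", reports$RSM$mean, 12.8402, 5e-5)
  add("validation_mean_lssvm", reports$`LS-SVM`$mean, 13.0045, 5e-5)
  add("relative_deviation_rsm",
      reports$RSM$relative_deviation_pct, 1.89, 0.01)
  add("relative_deviation_lssvm",
      reports$`LS-SVM`$relative_deviation_pct, 0.13, 0.01)
  cmp <- compare_models(reports)
  add("winner_is_lssvm", as.numeric(cmp$winner == "LS-SVM"), 1, 0)

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  report <- structure(list(checks = out, all_pass = all(out$pass),
                           anova = an, optimum = opt, comparison = cmp,
                           weights = weights$weights),
                      class = "reproduction_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(weights = as.list(weights$weights), checks = out,
           all_pass = report$all_pass),
      file.path(out_dir, "reproduction.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    write_anova(an, file.path(out_dir, "anova_table.csv"))
    say("report written", out_dir = out_dir)
  }
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  t <- x$checks
  cat(sprintf("Reproduction report: %d/%d checks pass\n",
              sum(t$pass), nrow(t)))
  for (i in seq_len(nrow(t)))
    cat(sprintf("  [%s] %-26s %12.6f (target %12.6f, tol %g)\n",
                if (t$pass[i]) "ok" else "FAIL", t$check[i], t$value[i],
                t$target[i], t$tol[i]))
  invisible(x)
}
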