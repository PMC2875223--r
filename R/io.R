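# Readers and writers: incidence CSV, the packaged SEER table, fit reports.

#' Read an age-grouped incidence table from CSV
#'
#' Expects a header with columns `age_lo`, `age_hi`, `n`, `y` (extra columns
#' are kept).  The table is validated: non-overlapping increasing age
#' groups, `0 <= y <= n`.
#'
#' @param path CSV file path.
#' @return An [incidence_table()].
#' @export
read_incidence_table <- function(path) {
  tab <- utils::read.csv(path)
  validate_incidence_table(tab)
}

#' @rdname read_incidence_table
#' @param table an [incidence_table()] to write.
#' @export
write_incidence_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' The packaged SEER colon cancer incidence table
#'
#' Age-grouped colon cancer incidence of the US SEER registry (overall
#' population, adjusted for genetic cases): 18 age groups with persons at
#' risk `n` and observed cases `y`.  The first two rows encode the
#' under-1 and 1-4 year groups as `[0, 1)` and `[1, 5)`; the remaining rows
#' span five years each.  The `predicted_ref` column carries the reference
#' model predictions published with the table.
#'
#' @return An [incidence_table()] with the extra `predicted_ref` column.
#' @export
seer_colon_table <- function() {
  path <- system.file("extdata", "seer_colon_incidence.csv",
                      package = "colonmsce", mustWork = TRUE)
  read_incidence_table(path)
}

#' Write a fit report (JSON + text table)
#'
#' Writes a machine-readable JSON report and a human-readable text table
#' next to it (same path with extension `.txt`): parameter estimates with
#' posterior standard deviations laid out per pathway and stage, deviance
#' and information criteria with their `(p, n)` conventions stated, and the
#' incidence table with the predicted column appended.
#'
#' @param fit a `colon_fit` from [gibbs_fit()].
#' @param path output path for the JSON report.
#' @return Invisibly, the paths written.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    converged = fit$converged,
    deviance = fit$deviance, AIC = fit$AIC, BIC = fit$BIC,
    p = fit$p, n_points = fit$n_points,
    estimates = as.list(fit$estimates),
    se = as.list(fit$se),
    n_draws = nrow(fit$draws),
    n_chains = fit$config$n_chains,
    seed = fit$seed,
    config = unclass(fit$config),
    table = as.data.frame(cbind(fit$table[, c("age_lo", "age_hi", "n", "y")],
                                predicted = fit$predicted))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- sub("\\.[^.]*$", "", path)
  txt <- paste0(txt, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  est <- fit$estimates; se <- fit$se
  fmt <- function(nm) sprintf("  %-9s %10.3e  +/- %9.3e", nm, est[[nm]],
                              se[[nm]])
  writeLines(c(
    "Two-pathway colon carcinogenesis model: parameter estimates",
    if (!fit$converged) "WARNING: fit flagged non-converged" else NULL,
    "",
    "CIN pathway (4 stages)",
    fmt("lambda_I"), fmt("alpha1"), fmt("alpha2"), fmt("alpha3"),
    fmt("b_I2"), fmt("gamma_I2"), fmt("delta1"), fmt("b_I3"), fmt("gamma_I3"),
    "",
    "MSI pathway (5 stages)",
    fmt("lambda_J"), fmt("beta1"), fmt("beta2"), fmt("beta3"), fmt("beta4"),
    fmt("b_J3"), fmt("gamma_J3"), fmt("delta2"), fmt("b_J4"), fmt("gamma_J4"),
    "",
    sprintf("Deviance = %.4f   AIC = %.4f   BIC = %.4f   (p = %d, n = %d)",
            fit$deviance, fit$AIC, fit$BIC, fit$p, fit$n_points),
    "",
    "Observed vs predicted cases",
    sprintf("  %5s-%-5s %12s %10s %12s", "from", "to", "at risk", "observed",
            "predicted"),
    sprintf("  %5g-%-5g %12.0f %10.0f %12.1f", fit$table$age_lo,
            fit$table$age_hi, fit$table$n, fit$table$y, fit$predicted)
  ), con)
  invisible(c(json = path, text = txt))
}

#' Reload the summary of a written fit report
#'
#' @param path JSON report path written by [write_fit_report()].
#' @return List with the report contents (estimates as a named vector).
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$estimates <- unlist(rep$estimates)
  rep$se <- unlist(rep$se)
  rep
}
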