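# Workbench: one-call drivers that wire the model and the trace pipeline
# together, with provenance, for reproducible runs.

.provenance <- function(seed = NULL, extra = list()) {
  c(list(package = "snarepore",
         version = as.character(utils::packageVersion("snarepore")),
         seed = seed),
    extra)
}

#' Desk-scale reproduction report
#'
#' Recomputes the model's headline quantities from scratch at the given
#' parameters and compares them with their reference values: the
#' conductance-to-radius conversion at 1 nS; the dilation sigmoid at 15
#' and 30 copies; the mean flicker count at the fitted geometric
#' parameter; the free-energy minimum radius; the net inward force with 0
#' and 15 SNAREs and their difference (the entropic contribution); the
#' tension/bending work decomposition over a 1 nm expansion; and the
#' lipid-anchor zippering-energy shift.
#'
#' @param params a \code{\link{model_params}}
#' @param seed integer seed recorded in the provenance block (the report
#'   itself is deterministic)
#' @param out_dir optional directory; when given, the report is written as
#'   \code{report.json} and \code{report.txt}
#' @param grid radius grid for the model profiles
#' @return data frame with one row per quantity: \code{target},
#'   \code{value}, \code{reference}, \code{tolerance}, \code{pass}; the
#'   provenance block is attached as an attribute
#' @export
run_reproduction_report <- function(params = model_params(), seed = 1L,
                                    out_dir = NULL,
                                    grid = default_radius_grid()) {
  rows <- list()
  add <- function(target, value, reference, tolerance)
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, value = value, reference = reference,
      tolerance = tolerance, pass = abs(value - reference) <= tolerance,
      stringsAsFactors = FALSE)

  add("radius_at_1nS_nm", radius_from_conductance(1000, 0.60), 1.7, 0.05)
  add("sigmoid_P15", eval_sigmoid(15, 19.3, 5.0), 0.30, 0.01)
  add("sigmoid_P30", eval_sigmoid(30, 19.3, 5.0), 0.90, 0.01)
  add("geometric_mean_flickers", (1 - 0.0573) / 0.0573, 16, 0.5)

  prof0 <- free_energy_profile(grid, 0, params)
  prof15 <- free_energy_profile(grid, 15, params)
  add("argmin_N0_nm", attr(prof0, "argmin"), 0.5, 0.15)
  f0 <- net_inward_force(prof0)
  f15 <- net_inward_force(prof15)
  add("net_force_N0_pN", f0, 22, 0.15 * 22)
  add("net_force_N15_pN", f15, 5, 0.15 * 5)
  add("snare_entropic_force_pN", f0 - f15, 17, 0.15 * 17)
  dec <- membrane_work_decomposition(params, r_from = attr(prof0, "argmin"))
  add("tension_work_1nm_kT", unname(dec["tension"]), 3.0, 0.2 * 3.0)
  add("bend_work_1nm_kT", unname(dec["bend"]), 2.4, 0.2 * 2.4)
  add("lipid_anchor_shift_kT", lipid_anchor_delta(params, grid = grid),
      0.43, 0.15)

  report <- do.call(rbind, rows)
  attr(report, "provenance") <- .provenance(seed, list(
    params = unclass(params)[names(formals(model_params))]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(provenance = attr(report, "provenance"),
                              targets = report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    txt <- c("snarepore reproduction report",
             sprintf("%-26s %12s %12s %10s %5s", "target", "value",
                     "reference", "tol", "pass"),
             sprintf("%-26s %12.4g %12.4g %10.3g %5s", report$target,
                     report$value, report$reference, report$tolerance,
                     report$pass))
    writeLines(txt, file.path(out_dir, "report.txt"))
  }
  report
}

#' Run the trace-analysis pipeline over a set of recordings
#'
#' Preprocesses each trace, idealizes it into pore records, and assembles
#' the cohort outputs: per-pore table, dwell-statistics fits, nucleation
#' rate, averaged conductance/radius distributions, the apparent
#' free-energy profile, and (when conditions span several SNARE copy
#' numbers) the dilation curve and sigmoid fit.
#'
#' @param traces list of \code{\link{current_trace}} objects, or a
#'   character vector of trace file paths (read with \code{\link{read_trace}})
#' @param N_per_face optional named vector mapping condition labels to
#'   SNARE copies per face (needed for the dilation fit)
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @param exclusions optional per-trace exclusion windows (see
#'   \code{\link{nucleation_rate}})
#' @param cutoff,block,notch filter settings passed to
#'   \code{\link{preprocess}}
#' @param ... idealization settings passed to \code{\link{idealize_trace}}
#' @return list with \code{records}, \code{table}, \code{flicker_fit},
#'   \code{lifetime_fit}, \code{nucleation}, \code{pdf_G}, \code{pdf_r},
#'   \code{energy}, and (when available) \code{dilation} and
#'   \code{sigmoid}
#' @export
run_pipeline <- function(traces, N_per_face = NULL, out_dir = NULL,
                         exclusions = NULL, cutoff = 280, block = 80,
                         notch = NULL, ...) {
  if (is.character(traces)) {
    if (!length(traces)) stop("no input traces", call. = FALSE)
    traces <- lapply(traces, function(f)
      tryCatch(read_trace(f),
               error = function(e) {
                 warning("skipping unreadable trace ", f, ": ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               }))
    traces <- Filter(Negate(is.null), traces)
  }
  if (!length(traces)) stop("no readable input traces", call. = FALSE)

  processed <- lapply(traces, preprocess, cutoff = cutoff, block = block,
                      notch = notch)
  bursts <- lapply(processed, detect_bursts)
  records <- unlist(lapply(processed, idealize_trace, ...), recursive = FALSE)
  durations <- vapply(traces, function(tr) length(tr$current) / tr$rate,
                      numeric(1))
  out <- list(records = records,
              table = if (length(records)) cohort_table(records) else NULL,
              nucleation = nucleation_rate(bursts, durations, exclusions))
  if (length(records) >= 5) {
    out$flicker_fit <- fit_flicker_geometric(records)
    out$lifetime_fit <- fit_burst_exponential(records)
  }
  with_samples <- Filter(function(r) length(r$G_samples) > 0, records)
  if (length(with_samples)) {
    out$pdf_G <- averaged_pdf(with_samples, "G")
    out$pdf_r <- averaged_pdf(with_samples, "r")
    out$energy <- data.frame(r_po = out$pdf_r$mids,
                             U = energy_from_pdf(out$pdf_r))
  }
  if (!is.null(N_per_face) && !is.null(out$table)) {
    tab <- out$table[!is.na(out$table$G_po), ]
    Nf <- N_per_face[as.character(tab$condition)]
    keep <- !is.na(Nf)
    if (sum(keep)) {
      labels <- classify_pores(tab$G_po[keep])
      out$dilation <- dilation_probability(labels, unname(Nf[keep]))
      if (length(unique(Nf[keep])) >= 3)
        out$sigmoid <- tryCatch(fit_dilation_sigmoid(out$dilation),
                                error = function(e) NULL)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$table))
      utils::write.csv(out$table, file.path(out_dir, "pores.csv"),
                       row.names = FALSE)
    if (!is.null(out$energy))
      utils::write.table(out$energy, file.path(out_dir, "energy_profile.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    summ <- list(provenance = .provenance(),
                 nucleation_rate_per_min = out$nucleation$rate,
                 n_pores = length(records),
                 flicker_p = out$flicker_fit$p,
                 mean_T0_s = out$lifetime_fit$mean_T0)
    if (!is.null(out$sigmoid))
      summ <- c(summ, list(N0 = out$sigmoid$N0, b_dil = out$sigmoid$b_dil,
                           r_squared = out$sigmoid$r_squared))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
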