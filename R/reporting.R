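# Report rendering. Display rounding (percentages 1 dp, relative risks
# 2 dp, weeks 1 dp) happens here and only here; stored CSVs keep full
# precision alongside.

#' Report configuration
#'
#' @param output_dir Directory the report files are written into (created
#'   if missing).
#' @param pct_digits,rr_digits,week_digits Display rounding (defaults 1, 2,
#'   1); applied at rendering only, never to stored values.
#' @return An object of class `report_config`.
#' @export
report_config <- function(output_dir, pct_digits = 1L, rr_digits = 2L,
                          week_digits = 1L) {
  structure(list(output_dir = output_dir, pct_digits = pct_digits,
                 rr_digits = rr_digits, week_digits = week_digits),
            class = "report_config")
}

.fmt_cell <- function(value, rr, pct_digits, rr_digits) {
  sprintf(paste0("%.", pct_digits, "f (%.", rr_digits, "f)"), value, rr)
}

#' Write heatmap-shaped tables for a grid result
#'
#' One wide CSV per outcome per panel (panel = high-wait / medium-increment
#' pair; rows = medium-tier size, columns = high-tier size; cells
#' `"value (RR)"`), the low-tier wait table in the same layout, the
#' full-precision `grid_results.csv`, and `grid_meta.json` (seed, reference
#' outcomes, config hash). Output is bit-stable given identical inputs.
#'
#' @param result A [run_grid()] result.
#' @param config A [report_config()].
#' @param config_hash Optional provenance hash recorded in the metadata.
#' @return Character vector of files written, invisibly.
#' @export
write_heatmap_tables <- function(result, config, config_hash = NA_character_) {
  stopifnot(inherits(result, "grid_result"), inherits(config, "report_config"))
  g <- result$table
  if (nrow(g) == 0L) stop("empty grid result", call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(config$output_dir, name)

  raw <- out("grid_results.csv")
  gw <- g
  num <- vapply(gw, is.double, logical(1))
  gw[num] <- lapply(gw[num], function(x) sprintf("%.17g", x))
  utils::write.csv(gw, raw, row.names = FALSE, quote = FALSE)
  files <- c(files, raw)

  three <- g[g$variant %in% c("three_group", "equal_thirds") & g$feasible, ]
  outcomes <- list(mortality = c("mortality_pct", "rr_mortality"),
                   hospitalization = c("hosp_pct", "rr_hosp"),
                   urgent = c("urgent_pct", "rr_urgent"))
  panels <- unique(three[c("high_wait", "medium_increment")])
  panels <- panels[order(panels$high_wait, panels$medium_increment), ]
  for (nm in names(outcomes)) {
    vcol <- outcomes[[nm]][1]; rcol <- outcomes[[nm]][2]
    for (j in seq_len(nrow(panels))) {
      p <- three[three$high_wait == panels$high_wait[j] &
                 three$medium_increment == panels$medium_increment[j] &
                 !is.na(three[[vcol]]), ]
      if (nrow(p) == 0L) next
      tab <- .panel_table(p, function(r)
        .fmt_cell(r[[vcol]], r[[rcol]], config$pct_digits, config$rr_digits))
      f <- out(sprintf("heatmap_%s_wt%g_inc%g.csv", nm,
                       panels$high_wait[j], panels$medium_increment[j]))
      utils::write.csv(tab, f, row.names = TRUE, quote = TRUE)
      files <- c(files, f)
    }
  }
  # low-tier wait layout (one table per panel)
  for (j in seq_len(nrow(panels))) {
    p <- three[three$high_wait == panels$high_wait[j] &
               three$medium_increment == panels$medium_increment[j], ]
    if (nrow(p) == 0L) next
    tab <- .panel_table(p, function(r)
      sprintf(paste0("%.", config$week_digits, "f"), r$solved_low_wait))
    f <- out(sprintf("low_wait_wt%g_inc%g.csv", panels$high_wait[j],
                     panels$medium_increment[j]))
    utils::write.csv(tab, f, row.names = TRUE, quote = TRUE)
    files <- c(files, f)
  }
  meta <- out("grid_meta.json")
  jsonlite::write_json(
    list(seed = result$seed,
         n_replicates = result$n_replicates,
         patients_per_replicate = result$patients_per_replicate,
         config_hash = config_hash,
         reference = list(
           mortality_pct = result$reference$mortality_pct,
           hospitalization_pct = result$reference$hospitalization_pct,
           urgent_pct = result$reference$urgent_pct)),
    meta, auto_unbox = TRUE, digits = NA)
  files <- c(files, meta)
  invisible(files)
}

.panel_table <- function(p, cell_fun) {
  ms <- sort(unique(p$medium_size))
  hs <- sort(unique(p$high_size))
  tab <- matrix("", nrow = length(ms), ncol = length(hs),
                dimnames = list(paste0("medium_", sprintf("%g", 100 * ms), "%"),
                                paste0("high_", sprintf("%g", 100 * hs), "%")))
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    tab[match(r$medium_size, ms), match(r$high_size, hs)] <- cell_fun(r)
  }
  as.data.frame(tab, stringsAsFactors = FALSE)
}

#' Rebuild a grid result from files written by [write_heatmap_tables()]
#'
#' Reads `grid_results.csv` and `grid_meta.json` back into a `grid_result`
#' (outcome summaries carry only the headline percentages). Used by the
#' `report` CLI stage and by round-trip checks.
#'
#' @param dir Directory containing the files.
#' @return A `grid_result`.
#' @export
read_grid_result <- function(dir) {
  raw <- file.path(dir, "grid_results.csv")
  meta_f <- file.path(dir, "grid_meta.json")
  for (f in c(raw, meta_f))
    if (!file.exists(f))
      stop("missing grid output file: ", f,
           " (run the grid stage first)", call. = FALSE)
  g <- utils::read.csv(raw)
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  reference <- outcome_summary(
    mortality_pct = meta$reference$mortality_pct,
    hospitalization_pct = meta$reference$hospitalization_pct,
    urgent_pct = meta$reference$urgent_pct,
    mean_realized_wait = NA_real_, mean_assigned_wait = NA_real_,
    per_group_waits = NULL, counts = NULL,
    n_replicates = meta$n_replicates)
  structure(list(table = g, reference = reference,
                 n_replicates = meta$n_replicates,
                 patients_per_replicate = meta$patients_per_replicate,
                 seed = meta$seed, hazards = NULL),
            class = "grid_result")
}
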