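# Cohort bookkeeping and report assembly. The cohort table is tidy: one row
# per (subject, protocol, condition, region, metric) with missingness
# allowed per cell; paired analyses use complete pairs per contrast, so
# different contrasts may be based on different n.

COHORT_COLS <- c("subject", "protocol", "condition", "region", "metric",
                 "value")
FF_CONDITIONS <- c("baseline", "cold1", "cold2", "reheated")
PET_CONDITIONS <- c("baseline", "cold1", "reheated")

#' Construct / validate a cohort table
#'
#' @param df data.frame with columns subject, protocol
#'   ("cooling-reheating" or "control"), condition ("baseline", "cold1",
#'   "cold2", "reheated"), region, metric ("FF", "MRglu", "perfusion",
#'   "VA"), value.
#' @return the validated data.frame (class `cohortTable`).
#' @export
cohortTable <- function(df) {
  if (!all(COHORT_COLS %in% names(df)))
    stop("cohort table needs columns: ", paste(COHORT_COLS, collapse = ", "))
  key <- do.call(paste, c(df[setdiff(COHORT_COLS, "value")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (subject, protocol, condition, region, metric) keys")
  class(df) <- c("cohortTable", "data.frame")
  df
}

#' Read / write a cohort table CSV
#'
#' @param df a cohort table.
#' @param path CSV file path.
#' @export
writeCohortTable <- function(df, path) {
  utils::write.csv(as.data.frame(df)[COHORT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) cohortTable(utils::read.csv(path))

# values for one cell type as a vector named by subject
cohortValues <- function(df, protocol, condition, region, metric,
                         subjects = NULL) {
  sel <- df$protocol == protocol & df$condition == condition &
    df$region == region & df$metric == metric
  v <- df$value[sel]
  names(v) <- df$subject[sel]
  if (is.null(subjects)) return(v)
  out <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  out[names(v)] <- v
  out
}

pFlag <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.05, "*",
                              ifelse(p < 0.10, "trend", "ns")))
}

#' Assemble the study report from a cohort table
#'
#' Produces (i) per-condition summaries by region with the paired
#' SAT-vs-sBAT and HI-vs-LO comparisons, (ii) correlations of FF and
#' perfusion against the cold MR_glu, and (iii) pairwise condition changes
#' with paired tests, the cooling-vs-control contrast, and the correlations
#' of changes with MR_glu and with the FF change. All tests are exact
#' small-sample Wilcoxon / Spearman; no multiple-comparison correction is
#' applied, and p-values in the trend band 0.05 <= p < 0.10 are flagged as
#' trends.
#'
#' @param table a cohort table (see [cohortTable()]).
#' @return list of data.frames (`summary`, `comparisons`, `correlations`,
#'   `changes`) with class `batReport`.
#' @export
buildReport <- function(table) {
  df <- as.data.frame(table)
  subj <- sort(unique(df$subject))
  cool <- "cooling-reheating"
  val <- function(cond, region, metric, protocol = cool)
    cohortValues(df, protocol, cond, region, metric, subjects = subj)

  mrglu <- list(sBAT = val("cold1", "sBAT", "MRglu"),
                sBAT_HI = val("cold1", "sBAT_HI", "MRglu"),
                sBAT_LO = val("cold1", "sBAT_LO", "MRglu"),
                SAT = val("cold1", "SAT", "MRglu"))

  # --- per-condition summaries + paired region comparisons -----------------
  summ <- NULL; comp <- NULL
  for (cond in FF_CONDITIONS) {
    for (region in c("SAT", "sBAT", "sBAT_HI", "sBAT_LO")) {
      v <- val(cond, region, "FF")
      summ <- rbind(summ, data.frame(
        condition = cond, metric = "FF", region = region,
        n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
        sd = stats::sd(v, na.rm = TRUE)))
    }
    for (pair in list(c("SAT", "sBAT"), c("sBAT_HI", "sBAT_LO"))) {
      a <- val(cond, pair[1L], "FF"); b <- val(cond, pair[2L], "FF")
      ok <- stats::complete.cases(a, b)
      if (sum(ok) >= 2L) {
        w <- wilcoxonSignedRank(a[ok], b[ok])
        comp <- rbind(comp, data.frame(
          condition = cond, metric = "FF",
          contrast = paste(pair, collapse = " vs "),
          p = w$p, n = sum(ok), flag = pFlag(w$p)))
      }
    }
  }
  for (metric in c("perfusion", "VA")) {
    for (cond in PET_CONDITIONS) {
      v <- val(cond, "sBAT", metric)
      summ <- rbind(summ, data.frame(
        condition = cond, metric = metric, region = "sBAT",
        n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
        sd = stats::sd(v, na.rm = TRUE)))
    }
  }

  # --- correlations against cold MR_glu ------------------------------------
  corr <- NULL
  addCorr <- function(cond, metric, region, v, m) {
    ok <- stats::complete.cases(v, m)
    if (sum(ok) < 3L) return()
    rc <- rankCorrelation(v[ok], m[ok])
    corr <<- rbind(corr, data.frame(
      condition = cond, metric = metric, region = region,
      rho = rc$spearman$rho, p_rho = rc$spearman$p,
      r = rc$pearson$r, p_r = rc$pearson$p, n = rc$n,
      flag = pFlag(rc$spearman$p)))
  }
  for (cond in FF_CONDITIONS)
    for (region in c("sBAT", "sBAT_HI", "sBAT_LO", "SAT"))
      addCorr(cond, "FF", region, val(cond, region, "FF"), mrglu[[region]])
  for (cond in PET_CONDITIONS)
    addCorr(cond, "perfusion", "sBAT", val(cond, "sBAT", "perfusion"),
            mrglu$sBAT)

  # --- pairwise condition changes ------------------------------------------
  changes <- NULL
  addChange <- function(metric, region, later, earlier) {
    a <- val(later, region, metric); b <- val(earlier, region, metric)
    dlt <- a - b
    ok <- !is.na(dlt)
    if (sum(ok) < 2L) return()
    w <- wilcoxonSignedRank(a[ok], b[ok])
    row <- data.frame(
      metric = metric, region = region,
      contrast = paste0(later, "-", earlier),
      delta = mean(dlt[ok]), sd = stats::sd(dlt[ok]), p = w$p,
      n = sum(ok), flag = pFlag(w$p),
      rho_mrglu = NA_real_, p_mrglu = NA_real_, n_mrglu = NA_integer_,
      rho_dff = NA_real_, p_dff = NA_real_, n_dff = NA_integer_,
      delta_control = NA_real_, n_control = NA_integer_,
      p_vs_control = NA_real_, n_vs_control = NA_integer_)
    m <- mrglu[[region]]
    if (!is.null(m)) {
      ok2 <- stats::complete.cases(dlt, m)
      if (sum(ok2) >= 3L) {
        rc <- rankCorrelation(dlt[ok2], m[ok2])
        row$rho_mrglu <- rc$spearman$rho
        row$p_mrglu <- rc$spearman$p
        row$n_mrglu <- rc$n
      }
    }
    if (metric %in% c("perfusion", "VA")) {
      dff <- val(later, "sBAT", "FF") - val(earlier, "sBAT", "FF")
      ok3 <- stats::complete.cases(dlt, dff)
      if (sum(ok3) >= 3L) {
        rc <- rankCorrelation(dlt[ok3], dff[ok3])
        row$rho_dff <- rc$spearman$rho
        row$p_dff <- rc$spearman$p
        row$n_dff <- rc$n
      }
    }
    if (metric == "FF" && region %in% c("sBAT", "SAT")) {
      ac <- val(later, region, metric, protocol = "control")
      bc <- val(earlier, region, metric, protocol = "control")
      dc <- ac - bc
      okc <- !is.na(dc)
      if (sum(okc) >= 2L) {
        row$delta_control <- mean(dc[okc])
        row$n_control <- sum(okc)
        both <- stats::complete.cases(dlt, dc)
        if (sum(both) >= 2L) {
          wd <- wilcoxonSignedRank(dlt[both], dc[both])
          row$p_vs_control <- wd$p
          row$n_vs_control <- sum(both)
        }
      }
    }
    changes <<- rbind(changes, row)
  }
  ffPairs <- list(c("cold1", "baseline"), c("cold2", "baseline"),
                  c("cold2", "cold1"), c("reheated", "baseline"),
                  c("reheated", "cold1"), c("reheated", "cold2"))
  for (pair in ffPairs)
    for (region in c("sBAT", "sBAT_HI", "sBAT_LO", "SAT"))
      addChange("FF", region, pair[1L], pair[2L])
  petPairs <- list(c("cold1", "baseline"), c("reheated", "baseline"),
                   c("reheated", "cold1"))
  for (pair in petPairs)
    for (metric in c("perfusion", "VA"))
      addChange(metric, "sBAT", pair[1L], pair[2L])

  structure(list(summary = summ, comparisons = comp, correlations = corr,
                 changes = changes),
            class = "batReport")
}

#' @export
print.batReport <- function(x, ...) {
  cat("BAT cooling-reheating report\n")
  cat("== Condition summaries ==\n")
  print(x$summary, digits = 3)
  cat("\n== Region comparisons (paired Wilcoxon) ==\n")
  print(x$comparisons, digits = 3)
  cat("\n== Correlations with cold MR_glu ==\n")
  print(x$correlations, digits = 3)
  cat("\n== Condition changes ==\n")
  print(x$changes[, c("metric", "region", "contrast", "delta", "sd", "p",
                      "n", "flag")], digits = 3)
  invisible(x)
}

#' Write a report to disk
#'
#' One CSV per report table plus a combined Markdown summary.
#'
#' @param report a `batReport` from [buildReport()].
#' @param dir output directory (created if needed).
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report))
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  md <- file.path(dir, "report.md")
  con <- file(md, "w")
  on.exit(close(con))
  for (nm in names(report)) {
    tab <- report[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) next
    writeLines(c(paste("##", nm), ""), con)
    writeLines(paste0("| ", paste(names(tab), collapse = " | "), " |"), con)
    writeLines(paste0("|", paste(rep("---", ncol(tab)), collapse = "|"),
                      "|"), con)
    for (i in seq_len(nrow(tab)))
      writeLines(paste0("| ", paste(vapply(tab[i, ], function(z)
        if (is.numeric(z)) formatC(z, digits = 3, format = "g")
        else as.character(z), character(1)), collapse = " | "), " |"), con)
    writeLines("", con)
  }
  invisible(dir)
}
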