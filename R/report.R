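.sigFlag <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Validate a stiffness table
#'
#' A stiffness table is a data frame with columns `subject_id`, `location`
#' (`upper`/`lower`), `status` (`normal`/`wound`/`after`), `device`
#' (`oct`/`reference`) and `k_value` (finite, positive), with at most one
#' row per (subject, location, status, device) cell.
#'
#' @param table a data frame.
#' @return the table, invisibly, or an error describing the defect.
#' @export
validateStiffnessTable <- function(table) {
  need <- c("subject_id", "location", "status", "device", "k_value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("validation error: missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(table$k_value)) || any(table$k_value <= 0)) {
    stop("validation error: k_value must be finite and positive")
  }
  key <- paste(table$subject_id, table$location, table$status, table$device)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (subject, location, status, device) rows")
  }
  invisible(table)
}

.cellValues <- function(table, device, location = NULL, status = NULL) {
  sel <- table$device == device
  if (!is.null(location)) sel <- sel & table$location == location
  if (!is.null(status)) sel <- sel & table$status == status
  sub <- table[sel, , drop = FALSE]
  sub[order(sub$subject_id), , drop = FALSE]
}

.se <- function(x) stats::sd(x) / sqrt(length(x))

#' Run the full stiffness comparison battery
#'
#' Produces the standard report tables over a stiffness table: per-status
#' upper-vs-lower Student's t-tests; per-location one-way ANOVA across the
#' three statuses with LSD post hoc contrasts; the two-way mixed ICC over
#' the six (status x location) conditions; Cohen's d effect sizes between
#' statuses and between locations; and per-condition Pearson correlations
#' between the two devices. p-values below 0.05 and 0.01 are flagged with
#' `*` and `**`. Contrasts whose cells are missing or too small are listed
#' in `skipped` and omitted rather than imputed.
#'
#' @param table a stiffness table (see [validateStiffnessTable()]).
#' @param alpha significance level used only for the flags (default 0.05).
#' @return a named list of data frames: `locationTTests`, `statusAnova`,
#'   `icc`, `effectSizeStatus`, `effectSizeLocation`, `correlation`,
#'   plus a character vector `skipped`.
#' @examples
#' tab <- simulateStiffnessTable(seed = 1)
#' rep <- analysisReport(tab)
#' rep$statusAnova
#' @export
analysisReport <- function(table, alpha = 0.05) {
  validateStiffnessTable(table)
  devices <- unique(table$device)
  statuses <- intersect(c("normal", "wound", "after"), unique(table$status))
  locations <- intersect(c("upper", "lower"), unique(table$location))
  skipped <- character()

  ## 1. upper vs lower Student's t per device x status
  ltt <- NULL
  for (dv in devices) {
    for (st in statuses) {
      up <- .cellValues(table, dv, "upper", st)$k_value
      lo <- .cellValues(table, dv, "lower", st)$k_value
      if (length(up) < 2L || length(lo) < 2L) {
        skipped <- c(skipped, sprintf("location t-test %s/%s (cell too small)", dv, st))
        next
      }
      tt <- studentsT(up, lo)
      ltt <- rbind(ltt, data.frame(
        device = dv, status = st,
        meanUpper = mean(up), seUpper = .se(up),
        meanLower = mean(lo), seLower = .se(lo),
        t = tt$t, p = tt$p, sig = .sigFlag(tt$p)
      ))
    }
  }

  ## 2. status ANOVA + LSD per device x location
  sa <- NULL
  if (length(statuses) < 2L) {
    warning("single status present; ANOVA sections skipped")
    skipped <- c(skipped, "status ANOVA (single status)")
  } else {
    for (dv in devices) {
      for (lc in locations) {
        gr <- lapply(statuses, function(st) .cellValues(table, dv, lc, st)$k_value)
        names(gr) <- statuses
        if (any(lengths(gr) < 2L)) {
          skipped <- c(skipped, sprintf("status ANOVA %s/%s (cell too small)", dv, lc))
          next
        }
        av <- onewayAnova(gr)
        lsd <- lsdPostHoc(gr, av$msError, av$dfError)
        row <- data.frame(device = dv, location = lc)
        for (st in statuses) {
          row[[paste0("mean_", st)]] <- mean(gr[[st]])
          row[[paste0("se_", st)]] <- .se(gr[[st]])
        }
        row$F <- av$F
        row$p <- av$p
        row$sig <- .sigFlag(av$p)
        for (r in seq_len(nrow(lsd))) {
          nm <- paste0("p_", statuses[lsd$i[r]], "_vs_", statuses[lsd$j[r]])
          row[[nm]] <- lsd$p[r]
          row[[paste0(nm, "_sig")]] <- .sigFlag(lsd$p[r])
        }
        sa <- rbind(sa, row)
      }
    }
  }

  ## 3. ICC over the status x location conditions per device
  iccDf <- NULL
  for (dv in devices) {
    conds <- expand.grid(status = statuses, location = locations,
                         stringsAsFactors = FALSE)
    cols <- list()
    subj <- NULL
    ok <- TRUE
    for (r in seq_len(nrow(conds))) {
      cell <- .cellValues(table, dv, conds$location[r], conds$status[r])
      if (is.null(subj)) subj <- cell$subject_id
      if (!identical(cell$subject_id, subj) || nrow(cell) < 2L) {
        ok <- FALSE
        break
      }
      cols[[paste(conds$status[r], conds$location[r], sep = "_")]] <- cell$k_value
    }
    if (!ok || length(cols) < 2L) {
      skipped <- c(skipped, sprintf("ICC %s (incomplete subject x condition matrix)", dv))
      next
    }
    icc <- iccTwoWayMixed(do.call(cbind, cols))
    iccDf <- rbind(iccDf, data.frame(
      device = dv, iccSingle = icc@iccSingle,
      ciSingleLo = icc@ciSingle[1], ciSingleHi = icc@ciSingle[2],
      iccAverage = icc@iccAverage,
      ciAverageLo = icc@ciAverage[1], ciAverageHi = icc@ciAverage[2]
    ))
  }

  ## 4. effect sizes between statuses per device x location
  esS <- NULL
  if (length(statuses) >= 2L) {
    pairsSt <- utils::combn(statuses, 2L)
    for (dv in devices) {
      for (lc in locations) {
        for (r in seq_len(ncol(pairsSt))) {
          a <- .cellValues(table, dv, lc, pairsSt[1L, r])$k_value
          b <- .cellValues(table, dv, lc, pairsSt[2L, r])$k_value
          if (length(a) < 2L || length(b) < 2L) next
          es <- cohensD(a, b)
          esS <- rbind(esS, data.frame(
            device = dv, location = lc,
            contrast = paste(pairsSt[1L, r], "vs", pairsSt[2L, r]),
            meanDiff = es@meanDifference, cohensD = es@cohensD,
            ciLo = es@ci95[1], ciHi = es@ci95[2]
          ))
        }
      }
    }
  }

  ## 5. effect sizes between locations per device x status
  esL <- NULL
  if (length(locations) == 2L) {
    for (dv in devices) {
      for (st in statuses) {
        a <- .cellValues(table, dv, "upper", st)$k_value
        b <- .cellValues(table, dv, "lower", st)$k_value
        if (length(a) < 2L || length(b) < 2L) next
        es <- cohensD(a, b)
        esL <- rbind(esL, data.frame(
          device = dv, status = st, meanDiff = es@meanDifference,
          cohensD = es@cohensD, ciLo = es@ci95[1], ciHi = es@ci95[2]
        ))
      }
    }
  }

  ## 6. device correlation per location x status
  corDf <- NULL
  if (all(c("oct", "reference") %in% devices)) {
    for (lc in locations) {
      for (st in statuses) {
        a <- .cellValues(table, "oct", lc, st)
        b <- .cellValues(table, "reference", lc, st)
        if (nrow(a) < 3L || !identical(a$subject_id, b$subject_id)) {
          skipped <- c(skipped, sprintf("correlation %s/%s (unpaired or too small)", lc, st))
          next
        }
        pc <- pearsonCorrelation(a$k_value, b$k_value)
        corDf <- rbind(corDf, data.frame(
          location = lc, status = st, r = pc$r, p = pc$p, sig = .sigFlag(pc$p)
        ))
      }
    }
  }

  list(
    locationTTests = ltt, statusAnova = sa, icc = iccDf,
    effectSizeStatus = esS, effectSizeLocation = esL,
    correlation = corDf, skipped = skipped
  )
}

#' Write a report to CSV files
#'
#' @param report the list returned by [analysisReport()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    locationTTests = "01_location_ttests.csv",
    statusAnova = "02_status_anova_lsd.csv",
    icc = "03_icc.csv",
    effectSizeStatus = "04_effect_size_status.csv",
    effectSizeLocation = "05_effect_size_location.csv",
    correlation = "06_device_correlation.csv"
  )
  for (nm in names(files)) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, files[nm]), row.names = FALSE)
    }
  }
  if (length(report$skipped)) {
    writeLines(report$skipped, file.path(dir, "skipped.txt"))
  }
  invisible(dir)
}

#' Simulate a repeated-measures stiffness table
#'
#' Generates a synthetic stiffness table emulating an air-jet indentation
#' study: every subject is measured at both limb locations in all three
#' statuses with both devices. Values are cell mean + subject random
#' intercept + residual noise; the reference device scales the same
#' underlying measurement into its own units with additional noise, giving
#' strongly correlated device readings. Default cell means put wound
#' stiffness above normal (more so in the lower limb) with post-treatment
#' values back near normal; they and the variance components emulate the
#' magnitudes reported for this kind of study.
#'
#' @param nSubjects subjects (default 14).
#' @param meanNormal,meanAfter status means common to both locations, N/mm.
#' @param meanWoundUpper,meanWoundLower wound means per location, N/mm.
#' @param subjectSd SD of the subject random intercept, N/mm.
#' @param noiseSd residual SD per measurement, N/mm.
#' @param refScale,refNoiseSd scale and added noise of the reference
#'   device (its units per N/mm, and SD in its own units).
#' @param seed integer seed.
#' @return a stiffness table data frame (see [validateStiffnessTable()]).
#' @examples
#' head(simulateStiffnessTable(seed = 1))
#' @export
simulateStiffnessTable <- function(nSubjects = 14L, meanNormal = 0.90,
                                   meanAfter = 0.95, meanWoundUpper = 1.30,
                                   meanWoundLower = 1.70, subjectSd = 0.25,
                                   noiseSd = 0.08, refScale = 460,
                                   refNoiseSd = 20, seed = 1L) {
  set.seed(as.integer(seed))
  cellMean <- function(status, location) {
    switch(status,
      normal = meanNormal,
      after = meanAfter,
      wound = if (location == "upper") meanWoundUpper else meanWoundLower
    )
  }
  subjEff <- stats::rnorm(nSubjects, 0, subjectSd)
  rows <- NULL
  for (s in seq_len(nSubjects)) {
    for (lc in c("upper", "lower")) {
      for (st in c("normal", "wound", "after")) {
        k <- cellMean(st, lc) + subjEff[s] + stats::rnorm(1, 0, noiseSd)
        k <- max(k, 0.05)
        ref <- max(k * refScale + stats::rnorm(1, 0, refNoiseSd), 1)
        rows <- rbind(rows, data.frame(
          subject_id = sprintf("S%02d", s), location = lc, status = st,
          device = c("oct", "reference"), k_value = c(k, ref)
        ))
      }
    }
  }
  rownames(rows) <- NULL
  rows
}
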