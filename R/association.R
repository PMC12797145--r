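# Association stage: the metric grid crossing fMRI metrics with EEG metrics,
# the linear mixed-effects fit Y ~ 1 + X + Sex + X:Sex with a participant
# random intercept, z-transform and 1.5 IQR outlier screening, BH false
# discovery control within each correction state, and the paired Wilcoxon
# comparison of adjusted r-squared before vs after correction.

#' Build the paired (Y, X) observation tables
#'
#' Merges the fMRI and EEG metric tables on (participant, network) and
#' returns one long table per (Y metric, X metric, correction state):
#' columns `participant`, `network`, `y`, `x`, `sex`. EEG metrics are
#' state-independent and are paired with every fMRI state.
#'
#' @param fmri_table,eeg_table Metric tables (see [metric_table()]).
#' @param sex_labels `data.frame(participant, sex)` with sex coded
#'   `+1`/`-1` (other binary codings are recoded).
#' @param y_metrics,x_metrics Metric subsets (defaults: all metrics present).
#' @param states Correction states (default: those present in `fmri_table`).
#' @return Named list (`"y|x|state"`) of merged data frames, with attributes
#'   `y_metrics`, `x_metrics`, `states`.
#' @export
build_grid <- function(fmri_table, eeg_table, sex_labels,
                       y_metrics = NULL, x_metrics = NULL, states = NULL) {
  if (is.null(y_metrics)) y_metrics <- unique(fmri_table$metric)
  if (is.null(x_metrics)) x_metrics <- unique(eeg_table$metric)
  if (is.null(states)) states <- unique(fmri_table$state)
  sex <- recode_sex(sex_labels$sex)
  names(sex) <- sex_labels$participant

  fkey <- unique(fmri_table[, c("participant", "network")])
  ekey <- unique(eeg_table[, c("participant", "network")])
  fk <- paste(fkey$participant, fkey$network)
  ek <- paste(ekey$participant, ekey$network)
  missing <- union(setdiff(fk, ek), setdiff(ek, fk))
  if (length(missing))
    stop("join error: (participant, network) keys missing from one table: ",
         paste(missing, collapse = ", "))

  out <- list()
  for (st in states) {
    fs <- fmri_table[fmri_table$state == st, ]
    for (y in y_metrics) {
      fy <- fs[fs$metric == y, c("participant", "network", "value")]
      names(fy)[3] <- "y"
      for (x in x_metrics) {
        ex <- eeg_table[eeg_table$metric == x, c("participant", "network", "value")]
        names(ex)[3] <- "x"
        m <- merge(fy, ex, by = c("participant", "network"))
        m$sex <- unname(sex[as.character(m$participant)])
        m <- m[complete.cases(m), ]
        m <- m[order(m$participant, m$network), ]
        rownames(m) <- NULL
        out[[paste(y, x, st, sep = "|")]] <- m
      }
    }
  }
  attr(out, "y_metrics") <- y_metrics
  attr(out, "x_metrics") <- x_metrics
  attr(out, "states") <- states
  out
}

recode_sex <- function(sex) {
  u <- sort(unique(sex))
  if (length(u) != 2L) stop("`sex` must be a binary covariate")
  ifelse(sex == u[2], 1, -1)
}

#' Standardize the model columns of a pair table
#'
#' Z-scores `y` and `x` (sample SD); sex is coded to `+1`/`-1` then
#' standardized. A zero-variance column raises a condition of class
#' `macrovasc_degenerate`, which the grid runner treats as "skip this pair".
#'
#' @param table A pair table from [build_grid()].
#' @return The table with standardized `y`, `x`, `sex`.
#' @export
zscore_columns <- function(table) {
  for (cn in c("y", "x", "sex")) {
    v <- if (cn == "sex") recode_sex(table$sex) else table[[cn]]
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop(structure(class = c("macrovasc_degenerate", "error", "condition"),
                     list(message = paste0("zero-variance column `", cn, "`"),
                          call = sys.call(-1))))
    table[[cn]] <- (v - mean(v)) / s
  }
  table
}

#' Remove IQR outliers from a pair table
#'
#' Drops rows where `y` or `x` lies outside
#' `[Q1 - k IQR, Q3 + k IQR]` (quartiles per column on this pair's table,
#' type-7 linear interpolation). Warns and flags when more than half the
#' rows are removed.
#'
#' @param table A pair table.
#' @param k Fence multiplier (default 1.5).
#' @return The table with outliers removed; attributes `n_removed` and
#'   `flagged`.
#' @export
remove_outliers_iqr <- function(table, k = 1.5) {
  keep <- rep(TRUE, nrow(table))
  for (cn in c("y", "x")) {
    q <- quantile(table[[cn]], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    keep <- keep & table[[cn]] >= q[1] - k * iqr & table[[cn]] <= q[2] + k * iqr
  }
  out <- table[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "flagged") <- FALSE
  if (sum(!keep) > nrow(table) / 2) {
    warning("more than 50% of rows removed as outliers")
    attr(out, "flagged") <- TRUE
  }
  out
}

#' Fit the mixed-effects association model for one pair
#'
#' Fits `y ~ 1 + x + sex + x:sex` with a participant random intercept
#' (optionally participant + network) by REML, and reports standardized
#' fixed effects with Satterthwaite p-values plus an adjusted r-squared
#' computed from the fixed-effects-only fitted values:
#' `1 - (1 - R2_marginal) (n - 1) / (n - p - 1)` with `p = 3` and
#' `R2_marginal = cor(y, yhat_fixed)^2`.
#'
#' @param table A standardized pair table (see [zscore_columns()]).
#' @param random Random-effect structure: `"participant"` (default) or
#'   `"participant_network"`.
#' @return One-row `data.frame` with effects, p-values, `r2_adj`, `n_used`,
#'   and `singular`/`converged` flags; effects are `NA` when the fit fails.
#' @export
fit_lme <- function(table, random = c("participant", "participant_network")) {
  random <- match.arg(random)
  if (length(unique(table$participant)) < 2L)
    stop("at least 2 participants are required")
  form <- if (random == "participant")
    y ~ x * sex + (1 | participant)
  else
    y ~ x * sex + (1 | participant) + (1 | network)
  res <- data.frame(beta_x = NA_real_, se_x = NA_real_, df_x = NA_real_,
                    p_x = NA_real_, beta_sex = NA_real_, p_sex = NA_real_,
                    beta_int = NA_real_, p_int = NA_real_, r2_adj = NA_real_,
                    n_used = nrow(table), singular = NA, converged = FALSE,
                    random = random, stringsAsFactors = FALSE)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = table,
                                    control = lme4::lmerControl(
                                      check.conv.singular = lme4::.makeCC(
                                        "ignore", tol = 1e-4)))),
    error = function(e) NULL)
  if (is.null(fit)) return(res)
  cs <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  if (is.null(cs) || !all(c("x", "sex", "x:sex") %in% rownames(cs))) return(res)
  yhat <- stats::model.matrix(fit) %*% lme4::fixef(fit)
  n <- nrow(table)
  r2m <- if (sd(yhat) == 0) 0 else cor(table$y, yhat)^2
  res$beta_x <- cs["x", "Estimate"]
  res$se_x <- cs["x", "Std. Error"]
  res$df_x <- cs["x", "df"]
  res$p_x <- cs["x", "Pr(>|t|)"]
  res$beta_sex <- cs["sex", "Estimate"]
  res$p_sex <- cs["sex", "Pr(>|t|)"]
  res$beta_int <- cs["x:sex", "Estimate"]
  res$p_int <- cs["x:sex", "Pr(>|t|)"]
  res$r2_adj <- 1 - (1 - r2m) * (n - 1) / (n - 1 - 3)
  res$singular <- lme4::isSingular(fit, tol = 1e-4)
  res$converged <- TRUE
  res
}

# Standardize -> screen outliers -> re-standardize -> fit. Returns NULL for
# degenerate (zero-variance) pairs.
fit_pair <- function(table, random = "participant", iqr_k = 1.5) {
  out <- tryCatch({
    tb <- zscore_columns(table)
    tb <- suppressWarnings(remove_outliers_iqr(tb, k = iqr_k))
    n_removed <- attr(tb, "n_removed")
    tb <- zscore_columns(tb)
    r <- fit_lme(tb, random = random)
    r$n_removed <- n_removed
    r
  }, macrovasc_degenerate = function(e) NULL)
  out
}

#' Benjamini-Hochberg false discovery control
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `q_values` (BH-adjusted) and logical `significant`
#'   (`q_values <= q`).
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (!length(p)) return(list(q_values = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  qv <- p.adjust(p, method = "BH")
  list(q_values = qv, significant = !is.na(qv) & qv <= q)
}

#' Paired Wilcoxon signed-rank comparison of goodness-of-fit
#'
#' Two-sided Wilcoxon signed-rank test on `post - pre`, pairs matched by
#' position. Zero differences are dropped before ranking; the exact null is
#' used for up to 25 non-zero differences without ties, the normal
#' approximation with continuity correction otherwise. When every
#' difference is zero the p-value is reported as 1 with a flag.
#'
#' @param pre_r2,post_r2 Paired numeric vectors (length >= 6).
#' @return List with `statistic` (V), `p_value`, `n_effective`,
#'   `median_difference`, and `degenerate`.
#' @export
compare_r2 <- function(pre_r2, post_r2) {
  if (length(pre_r2) != length(post_r2)) stop("paired vectors differ in length")
  ok <- is.finite(pre_r2) & is.finite(post_r2)
  d <- post_r2[ok] - pre_r2[ok]
  if (length(d) < 6L) stop("at least 6 pairs are required")
  dz <- d[d != 0]
  if (!length(dz))
    return(list(statistic = NA_real_, p_value = 1, n_effective = 0L,
                median_difference = 0, degenerate = TRUE))
  exact <- length(dz) <= 25L && !any(duplicated(abs(dz)))
  wt <- suppressWarnings(wilcox.test(dz, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = length(dz), median_difference = median(d),
       degenerate = FALSE)
}

#' Fit every pair of the association grid
#'
#' Runs the standardize/screen/fit pipeline for every (Y, X, state) table
#' and applies BH false discovery control at level `q` separately within
#' each correction state's family (independently for the X, Sex and X:Sex
#' p-values).
#'
#' @param grid Output of [build_grid()].
#' @param q FDR level (default 0.05).
#' @param random Random-effect structure passed to [fit_lme()].
#' @param iqr_k IQR fence multiplier (default 1.5).
#' @return `data.frame` with one row per fitted pair: identifiers, effects,
#'   p-values, `q_*` adjusted values and `sig_*` flags, `r2_adj`, `n_used`.
#' @export
run_associations <- function(grid, q = 0.05, random = "participant",
                             iqr_k = 1.5) {
  keys <- names(grid)
  rows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], "|", fixed = TRUE)[[1]]
    r <- fit_pair(grid[[keys[i]]], random = random, iqr_k = iqr_k)
    if (is.null(r)) next
    rows[[i]] <- cbind(data.frame(y = parts[1], x = parts[2], state = parts[3],
                                  stringsAsFactors = FALSE), r)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  for (eff in c("x", "sex", "int")) {
    pcol <- paste0("p_", eff)
    out[[paste0("q_", eff)]] <- NA_real_
    out[[paste0("sig_", eff)]] <- NA
    for (st in unique(out$state)) {
      sel <- out$state == st
      fc <- fdr_correct(out[[pcol]][sel], q = q)
      out[[paste0("q_", eff)]][sel] <- fc$q_values
      out[[paste0("sig_", eff)]][sel] <- fc$significant
    }
  }
  out
}

#' Signed-polarity matrix of significant associations
#'
#' Rows are fMRI metrics, columns EEG metrics; entries are the sign of the
#' standardized X effect where it survives FDR in the given state, 0
#' otherwise.
#'
#' @param associations Output of [run_associations()].
#' @param state Correction state to summarize (default `"post"`).
#' @return Integer matrix in `{-1, 0, 1}`.
#' @export
polarity_matrix <- function(associations, state = "post") {
  a <- associations[associations$state == state, ]
  ys <- unique(a$y)
  xs <- unique(a$x)
  m <- matrix(0L, length(ys), length(xs), dimnames = list(ys, xs))
  sig <- !is.na(a$sig_x) & a$sig_x
  for (i in which(sig)) m[a$y[i], a$x[i]] <- as.integer(sign(a$beta_x[i]))
  m
}
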