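#' Two-way fully within-subject repeated-measures ANOVA
#'
#' Standard balanced within-subject decomposition for two crossed
#' repeated-measures factors (e.g., model family and accelerometer
#' measurement range), with the subject-by-effect interaction as each
#' effect's error term. Sphericity is addressed with the Greenhouse-Geisser
#' correction: each effect's epsilon is the Box estimate computed from the
#' sample covariance of that effect's orthonormal contrast scores, and the F
#' test is referred to epsilon-scaled degrees of freedom.
#'
#' @param tbl data.frame with one row per subject x cell.
#' @param subject,f1,f2,response Column names of the subject id, the two
#'   within factors, and the numeric response (e.g., per-subject F1 or MAE).
#' @return data.frame with one row per effect (`f1`, `f2`, interaction):
#'   sums of squares and df for the effect and its error term, F, epsilon,
#'   GG-corrected dfs and p, and the uncorrected p.
#' @export
rm_anova_two_way <- function(tbl, subject = "subject_id", f1 = "model",
                             f2 = "range", response = "value") {
  a_lv <- sort(unique(as.character(tbl[[f1]])))
  b_lv <- sort(unique(as.character(tbl[[f2]])))
  s_lv <- unique(as.character(tbl[[subject]]))
  a <- length(a_lv); b <- length(b_lv); n <- length(s_lv)
  if (n < 3) stop("need >= 3 subjects")
  # complete balanced crossing: one response per subject x cell
  key <- interaction(tbl[[subject]], tbl[[f1]], tbl[[f2]], drop = FALSE)
  counts <- table(factor(tbl[[subject]], s_lv),
                  factor(tbl[[f1]], a_lv), factor(tbl[[f2]], b_lv))
  if (any(counts != 1)) {
    miss <- which(counts != 1, arr.ind = TRUE)
    stop("balance error: each subject needs exactly one response per cell; ",
         "first bad cell: subject=", s_lv[miss[1, 1]], " ", f1, "=",
         a_lv[miss[1, 2]], " ", f2, "=", b_lv[miss[1, 3]])
  }
  if (any(!is.finite(tbl[[response]]))) stop("non-finite response values")

  # subject x cell matrix, cells ordered (a slow, b fast)
  Y <- matrix(NA_real_, n, a * b)
  cell <- (match(as.character(tbl[[f1]]), a_lv) - 1L) * b +
    match(as.character(tbl[[f2]]), b_lv)
  Y[cbind(match(as.character(tbl[[subject]]), s_lv), cell)] <- tbl[[response]]

  grand <- mean(Y)
  m_s <- rowMeans(Y)
  m_ab <- colMeans(Y)
  cell_a <- rep(seq_len(a), each = b)
  cell_b <- rep(seq_len(b), times = a)
  m_a <- tapply(m_ab, cell_a, mean)
  m_b <- tapply(m_ab, cell_b, mean)
  # per-subject factor means
  m_as <- t(apply(Y, 1, function(r) tapply(r, cell_a, mean)))
  m_bs <- t(apply(Y, 1, function(r) tapply(r, cell_b, mean)))

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - m_a[cell_a] - m_b[cell_b] + grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_as <- b * sum((m_as - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- a * sum((m_bs - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  # orthonormal within-cell contrasts per effect
  ortho <- function(k) {
    M <- stats::contr.helmert(k)
    t(M) / sqrt(colSums(M^2))
  }
  avg <- function(k) matrix(1 / k, 1, k)
  eff_T <- list(
    ortho(a) %x% avg(b),      # f1
    avg(a) %x% ortho(b),      # f2
    ortho(a) %x% ortho(b)     # interaction
  )
  eps <- vapply(eff_T, function(Tm) {
    Z <- Y %*% t(Tm)
    S <- stats::cov(Z)
    d <- nrow(Tm)
    if (d == 1) 1 else sum(diag(S))^2 / (d * sum(S^2))
  }, numeric(1))

  df_eff <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_err <- df_eff * (n - 1)
  ss_eff <- c(ss_a, ss_b, ss_ab)
  ss_err <- c(ss_as, ss_bs, ss_abs)
  Fval <- (ss_eff / df_eff) / (ss_err / df_err)
  p_unc <- stats::pf(Fval, df_eff, df_err, lower.tail = FALSE)
  p_gg <- stats::pf(Fval, eps * df_eff, eps * df_err, lower.tail = FALSE)

  data.frame(
    effect = c(f1, f2, paste0(f1, ":", f2)),
    ss = ss_eff, df = df_eff, error_ss = ss_err, error_df = df_err,
    F = Fval, epsilon = eps,
    df_gg = eps * df_eff, error_df_gg = eps * df_err,
    p_gg = p_gg, p_uncorrected = p_unc,
    stringsAsFactors = FALSE
  )
}

#' Cell and margin means of a balanced repeated-measures table
#'
#' With a complete balanced crossing these equal the model-estimated means of
#' the within-subject ANOVA.
#'
#' @inheritParams rm_anova_two_way
#' @return List with `cells` (f1 x f2 means), `margin_f1`, `margin_f2`
#'   (data.frames of level and mean), and `grand` (grand mean).
#' @export
marginal_means <- function(tbl, f1 = "model", f2 = "range",
                           response = "value") {
  cells <- stats::aggregate(tbl[[response]],
                            by = list(tbl[[f1]], tbl[[f2]]), FUN = mean)
  names(cells) <- c(f1, f2, "mean")
  m1 <- stats::aggregate(tbl[[response]], by = list(tbl[[f1]]), FUN = mean)
  names(m1) <- c(f1, "mean")
  m2 <- stats::aggregate(tbl[[response]], by = list(tbl[[f2]]), FUN = mean)
  names(m2) <- c(f2, "mean")
  list(cells = cells, margin_f1 = m1, margin_f2 = m2,
       grand = mean(tbl[[response]]))
}

#' Holm step-down adjustment of p-values
#'
#' @param p Raw p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("contract error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Paired high-g vs low-g contrasts within strata, Holm-adjusted
#'
#' For each stratum (e.g., model family or predicted class), forms the
#' per-subject difference (high_g minus low_g) of the response, tests it with
#' a paired t-test, and Holm-adjusts the p-values across strata.
#'
#' @param tbl data.frame with subject, stratum, range, and response columns.
#' @param stratum Column name of the stratum factor.
#' @param subject,response Column names.
#' @param range_col Column with exactly two levels; the difference is
#'   `levels[1] - levels[2]` after sorting with "high_g" first if present.
#' @return data.frame with one row per stratum: `estimate` (mean paired
#'   difference), `n` subjects, `p_raw`, `p_holm`.
#' @export
paired_range_contrast <- function(tbl, stratum, subject = "subject_id",
                                  range_col = "range", response = "value") {
  lv <- sort(unique(as.character(tbl[[range_col]])))
  if (length(lv) != 2) stop("range column must have exactly two levels")
  if ("high_g" %in% lv) lv <- c("high_g", setdiff(lv, "high_g"))
  strata <- unique(as.character(tbl[[stratum]]))
  rows <- lapply(strata, function(st) {
    d <- tbl[tbl[[stratum]] == st, ]
    hi <- d[d[[range_col]] == lv[1], c(subject, response)]
    lo <- d[d[[range_col]] == lv[2], c(subject, response)]
    m <- merge(hi, lo, by = subject, suffixes = c(".hi", ".lo"))
    dropped <- setdiff(unique(c(hi[[subject]], lo[[subject]])), m[[subject]])
    if (length(dropped) > 0) {
      message("dropping subject(s) without both range levels in stratum '",
              st, "': ", paste(dropped, collapse = ", "))
    }
    diffs <- m[[paste0(response, ".hi")]] - m[[paste0(response, ".lo")]]
    p <- if (stats::sd(diffs) < 1e-15) {
      if (mean(diffs) == 0) 1 else 0
    } else stats::t.test(diffs)$p.value
    data.frame(stratum = st, estimate = mean(diffs), n = length(diffs),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}
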