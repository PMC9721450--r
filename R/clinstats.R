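#' Chi-square test on an r x 2 contingency table
#'
#' Pearson chi-square on benign/malignant count columns; 2 x 2 tables use
#' the Yates continuity correction (|O - E| - 0.5), larger tables the plain
#' Pearson statistic — the convention of standard clinical reporting.
#'
#' @param counts matrix or data.frame with >= 2 rows (categories) and 2
#'   columns of nonnegative integer counts (benign, malignant); empty cells
#'   ("Nil") are structural zeros
#' @return an object of class `chisq_result`: `chi2`, `df`, `p`, `corrected`
#' @export
chi_square <- function(counts) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) != 2)
    stop("counts must have >= 2 rows and exactly 2 columns", call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0))
    stop("zero row total in row ", which(rs == 0)[1], call. = FALSE)
  if (any(cs == 0))
    stop("zero column total in column ", which(cs == 0)[1], call. = FALSE)
  corrected <- nrow(m) == 2
  res <- suppressWarnings(stats::chisq.test(m, correct = corrected))
  structure(list(chi2 = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, corrected = corrected),
            class = "chisq_result")
}

#' @exportS3Method base::print
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g (df = %d%s), p = %.4g\n", x$chi2, x$df,
              if (x$corrected) ", Yates-corrected" else "", x$p))
  invisible(x)
}

#' Two-tailed two-sample t test (pooled variance)
#'
#' @param x,y numeric samples (each of size >= 2)
#' @return list with `t`, `df`, `p`
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs >= 2 observations", call. = FALSE)
  df <- length(x) + length(y) - 2
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    t <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    return(list(t = t, df = df, p = if (t == 0) 1 else 0))
  }
  res <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter), p = res$p.value)
}

#' Published clinical-characteristics counts
#'
#' The benign/malignant contingency tables of the study cohort (1298
#' patients: 771 benign, 527 malignant): age bands, mass size and BI-RADS
#' breast composition type. The empty "Nil" cell (malignant, age <= 20) is a
#' structural zero.
#'
#' @return named list of count matrices (`age`, `size`, `composition`),
#'   columns benign/malignant
#' @export
clinical_table1_counts <- function() {
  list(
    age = matrix(c(18, 348, 383, 22, 0, 66, 332, 129), ncol = 2,
                 dimnames = list(c("<=20", "20-40", "40-60", ">60"),
                                 c("benign", "malignant"))),
    size = matrix(c(475, 296, 207, 320), ncol = 2,
                  dimnames = list(c("<=20mm", ">20mm"),
                                  c("benign", "malignant"))),
    composition = matrix(c(9, 37, 666, 59, 23, 74, 417, 13), ncol = 2,
                         dimnames = list(c("A", "B", "C", "D"),
                                         c("benign", "malignant"))))
}
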