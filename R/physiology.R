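#' Specific rates and yields for steady-state chemostat samples
#'
#' At chemostat steady state the dilution rate D equals the specific growth
#' rate, and mass balances over the vessel give the specific rates directly
#' from broth concentrations:
#' \deqn{SPPR = 1000 \cdot D P / X}{SPPR = 1000 * D * P / X}
#' \deqn{q_s = D (S_{feed} - S_{res}) / X}
#' \deqn{Y_{xs} = X / (S_{feed} - S_{res}), \quad
#'       Y_{ps} = P / (S_{feed} - S_{res})}
#' where D is the dilution rate (1/h), X the biomass dry weight (g/L), P the
#' extracellular protein (g/L) and S the growth-limiting substrate (g/L).
#' SPPR, the specific extracellular protein production rate, is reported in
#' mg protein / g biomass / h (hence the factor 1000).
#'
#' @param cultivations data.frame with columns \code{sample_id},
#'   \code{condition}, \code{D}, \code{X}, \code{P}, \code{S_feed},
#'   \code{S_res}.  Residual substrate below detection should be coded 0.
#' @return the input with derived columns \code{SPPR}, \code{q_s},
#'   \code{Y_xs}, \code{Y_ps} appended.
#' @examples
#' computeRates(data.frame(sample_id = "a", condition = "D03", D = 0.03,
#'                         X = 5, P = 0.5, S_feed = 10, S_res = 0))
#' @export
computeRates <- function(cultivations) {
    cu <- as.data.frame(cultivations)
    req <- c("sample_id", "condition", "D", "X", "P", "S_feed", "S_res")
    miss <- setdiff(req, colnames(cu))
    if (length(miss))
        stop("cultivation table lacks column(s): ",
             paste(miss, collapse = ", "))
    bad <- cu$X <= 0
    if (any(bad))
        stop("non-positive biomass dry weight for sample(s): ",
             paste(cu$sample_id[bad], collapse = ", "))
    if (any(cu$D <= 0))
        stop("non-positive dilution rate for sample(s): ",
             paste(cu$sample_id[cu$D <= 0], collapse = ", "))
    if (any(cu$S_res > cu$S_feed))
        stop("residual substrate exceeds feed for sample(s): ",
             paste(cu$sample_id[cu$S_res > cu$S_feed], collapse = ", "))
    dS <- cu$S_feed - cu$S_res
    if (any(dS == 0))
        stop("zero substrate consumption for sample(s): ",
             paste(cu$sample_id[dS == 0], collapse = ", "))
    cu$SPPR <- 1000 * cu$D * cu$P / cu$X
    cu$q_s <- cu$D * dS / cu$X
    cu$Y_xs <- cu$X / dS
    cu$Y_ps <- cu$P / dS
    cu
}

#' Two-sample comparison of a cultivation parameter between conditions
#'
#' Student's two-sample t-test (pooled variance by default, Welch optional)
#' on a derived or measured field, e.g. the biomass yield difference between
#' two dilution-rate conditions.
#'
#' @param cultivations data.frame as returned by \code{\link{computeRates}}.
#' @param field column to compare.
#' @param groupA,groupB condition labels.
#' @param welch if \code{TRUE}, use the Welch (unequal-variance) statistic.
#' @return list with \code{difference} (mean of A minus mean of B),
#'   \code{p.value}, \code{statistic} and \code{df}.
#' @export
conditionContrast <- function(cultivations, field, groupA, groupB,
                              welch = FALSE) {
    cu <- as.data.frame(cultivations)
    if (!field %in% colnames(cu)) stop("unknown field: ", field)
    a <- cu[[field]][cu$condition == groupA]
    b <- cu[[field]][cu$condition == groupB]
    if (length(a) < 2 || length(b) < 2)
        stop("need at least 2 samples per group")
    tt <- stats::t.test(a, b, var.equal = !welch)
    list(difference = mean(a) - mean(b),
         p.value = tt$p.value,
         statistic = unname(tt$statistic),
         df = unname(tt$parameter))
}
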