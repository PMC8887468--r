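#' Empirical-Bayes variance hyperparameters
#'
#' Fits the scaled inverse-chi-square prior of the moderated t-test by
#' method of moments on the log residual variances: writing
#' \eqn{z_g = \log s_g^2}, the identities
#' \eqn{E[z_g] = \log s^2 + \psi(d/2) - \log(d/2)} and
#' \eqn{Var[z_g] = \psi'(d/2)} for log-chi-square variables give the prior
#' degrees of freedom \code{d0} from the excess of the observed variance of
#' \eqn{z_g} over its sampling variance (via the inverse trigamma), and the
#' prior variance \code{s0Sq} from the mean. If there is no excess
#' variability the prior is degenerate: \code{d0 = Inf} (complete
#' shrinkage) with \code{s0Sq} the common variance.
#'
#' @param s2 per-window residual variances.
#' @param df residual degrees of freedom (scalar or per-window).
#' @return list of class \code{"EBayesHyperparams"} with \code{d0} and
#'   \code{s0Sq}.
#' @seealso \code{\link{moderatedT}}
#' @export
fitEBayes <- function(s2, df) {
  s2 <- pmax(s2, 1e-8)
  ok <- is.finite(s2)
  stopifnot2(sum(ok) >= 2, "at least 2 finite variances are required")
  s2 <- s2[ok]
  df <- rep_len(df, length(ok))[ok]
  if (length(unique(s2)) == 1L) {
    # no variability at all: degenerate prior at the common variance
    return(structure(list(d0 = Inf, s0Sq = s2[1]), class = "EBayesHyperparams"))
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  n <- length(e)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (n - 1)
  excess <- evar - mean(trigamma(df / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigammaInverse(excess)
    s0Sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0Sq <- exp(ebar)
  }
  structure(list(d0 = d0, s0Sq = s0Sq), class = "EBayesHyperparams")
}

# Newton solve of trigamma(y) = x; trigamma is convex decreasing so the
# multiplicative Newton step on 1/trigamma converges fast.
trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-sample t-test
#'
#' Pooled per-window residual variance with \code{dg = nA + nB - 2} degrees
#' of freedom is shrunk toward the prior:
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, and the
#' statistic \eqn{t = \Delta / (\tilde s \sqrt{1/n_A + 1/n_B})} is referred
#' to a Student t with \code{d0 + dg} degrees of freedom (Gaussian when
#' \code{d0 = Inf}; the ordinary pooled t when \code{d0 = 0}).
#'
#' @param valuesA,valuesB matrices (windows x replicates) for the two
#'   groups; the effect is \code{B - A}.
#' @param hp hyperparameters from \code{\link{fitEBayes}} (or a list with
#'   \code{d0}, \code{s0Sq}).
#' @return data.frame with \code{meanA}, \code{meanB}, \code{delta},
#'   \code{s2}, \code{tMod}, \code{dfTotal}, \code{p}.
#' @export
moderatedT <- function(valuesA, valuesB, hp) {
  valuesA <- as.matrix(valuesA); valuesB <- as.matrix(valuesB)
  nA <- ncol(valuesA); nB <- ncol(valuesB)
  stopifnot2(nA >= 2 && nB >= 2, "at least 2 replicates per group are required")
  mA <- rowMeans(valuesA); mB <- rowMeans(valuesB)
  ssA <- rowSums((valuesA - mA)^2); ssB <- rowSums((valuesB - mB)^2)
  dg <- nA + nB - 2
  s2 <- pmax((ssA + ssB) / dg, 1e-8)
  d0 <- hp$d0; s0 <- hp$s0Sq
  stilde2 <- if (is.infinite(d0)) rep(s0, length(s2)) else {
    (d0 * s0 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(stilde2 * (1 / nA + 1 / nB))
  t <- (mB - mA) / se
  dfTotal <- d0 + dg
  p <- if (is.infinite(dfTotal)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df = dfTotal)
  data.frame(meanA = mA, meanB = mB, delta = mB - mA, s2 = s2,
             tMod = t, dfTotal = dfTotal, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved and \code{NA} p-values propagate as \code{NA}
#' without counting toward the number of tests.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values, same length and order.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Differential-enrichment calling over windows
#'
#' The window-level two-group analysis: fits the empirical-Bayes variance
#' prior genome-wide, computes the moderated t for every window, adjusts by
#' Benjamini-Hochberg and assigns each significant window a direction (gain
#' if the knockout-minus-control difference is positive, loss if negative).
#'
#' @param qm \linkS4class{QuantMatrix} of kind \code{"log2_norm"} over the
#'   artifact-filtered valid windows, per-replicate columns.
#' @param groups two-level factor over samples; the first level is the
#'   reference (control) group, effects are second minus first.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame of class \code{"DiffCalls"}: window id, coordinates,
#'   group means, \code{delta}, \code{tMod}, \code{p}, \code{q},
#'   \code{direction}; attributes \code{hyperparams} and
#'   \code{fractionCalled} (fraction of tested windows called).
#' @export
callDifferentialWindows <- function(qm, groups, alpha = 0.05) {
  stopifnot2(valueKind(qm) == "log2_norm",
             "callDifferentialWindows expects a log2_norm QuantMatrix")
  groups <- as.factor(groups)
  stopifnot2(nlevels(groups) == 2, "exactly two groups are required")
  stopifnot2(all(table(groups) >= 2), "at least 2 replicates per group are required")
  v <- quantValues(qm)
  A <- v[, groups == levels(groups)[1], drop = FALSE]
  B <- v[, groups == levels(groups)[2], drop = FALSE]
  dg <- ncol(A) + ncol(B) - 2
  mA <- rowMeans(A); mB <- rowMeans(B)
  s2 <- pmax((rowSums((A - mA)^2) + rowSums((B - mB)^2)) / dg, 1e-8)
  hp <- fitEBayes(s2, dg)
  res <- moderatedT(A, B, hp)
  res$q <- bhAdjust(res$p)
  res$direction <- ifelse(res$q < alpha & res$delta > 0, "gain",
                   ifelse(res$q < alpha & res$delta < 0, "loss", "none"))
  w <- SummarizedExperiment::rowRanges(qm)
  out <- data.frame(
    id = names(w),
    chrom = as.character(GenomeInfoDb::seqnames(w)),
    start = GenomicRanges::start(w),
    end = GenomicRanges::end(w),
    res,
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "meanA"] <- paste0("mean_", levels(groups)[1])
  names(out)[names(out) == "meanB"] <- paste0("mean_", levels(groups)[2])
  attr(out, "hyperparams") <- hp
  attr(out, "fractionCalled") <- mean(out$direction != "none")
  class(out) <- c("DiffCalls", "data.frame")
  out
}

# GRanges of the called windows in one direction.
diffCallRanges <- function(calls, direction) {
  sel <- calls[calls$direction == direction, , drop = FALSE]
  gr <- GenomicRanges::GRanges(sel$chrom, IRanges::IRanges(sel$start, sel$end))
  names(gr) <- sel$id
  gr
}
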