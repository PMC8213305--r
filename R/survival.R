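# Survival analysis: Kaplan-Meier with median-split log-rank, Cox
# proportional-hazards module risk scores, and time-dependent ROC/AUC
# (cumulative/dynamic, Kaplan-Meier estimator).

#' @importFrom survival Surv survfit survdiff coxph coxph.control
NULL

.surv_df <- function(clin, sampleIds = NULL) {
    clin <- validateClinicalTable(clin)
    if (!is.null(sampleIds)) {
        miss <- setdiff(sampleIds, clin$sample_id)
        if (length(miss))
            stop("sample(s) missing from clinical table: ",
                 paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
        clin <- clin[match(sampleIds, clin$sample_id), , drop = FALSE]
    }
    clin
}

#' Kaplan-Meier product-limit fit per group
#'
#' @param clin clinical `data.frame(sample_id, time, event)`.
#' @param group named character vector (or vector aligned with `clin`)
#'   assigning each sample to a group.
#' @return a [survival::survfit] object (strata = groups).
#' @export
kmFit <- function(clin, group) {
    clin <- .surv_df(clin)
    g <- if (!is.null(names(group))) group[clin$sample_id] else group
    if (anyNA(g) || any(!nzchar(g))) {
        bad <- clin$sample_id[is.na(g) | !nzchar(g)]
        stop("no group for sample(s): ",
             paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
    tab <- table(g)
    if (any(tab == 0)) stop("empty group: ", names(tab)[tab == 0][1],
                            call. = FALSE)
    df <- data.frame(time = clin$time, event = clin$event, g = factor(g))
    survfit(Surv(time, event) ~ g, data = df)
}

#' Log-rank test between two groups
#'
#' Chi-square statistic on 1 degree of freedom with its two-sided p.
#'
#' @inheritParams kmFit
#' @return an `"htest"` with `statistic` (chisq) and `p.value`.
#' @export
logrankTest <- function(clin, group) {
    clin <- .surv_df(clin)
    g <- if (!is.null(names(group))) group[clin$sample_id] else group
    if (length(unique(g)) != 2)
        stop("log-rank test requires exactly 2 groups, got ",
             length(unique(g)), call. = FALSE)
    df <- data.frame(time = clin$time, event = clin$event, g = factor(g))
    sd <- survdiff(Surv(time, event) ~ g, data = df)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    structure(list(statistic = c(chisq = unname(sd$chisq)),
                   parameter = c(df = 1), p.value = p,
                   method = "log-rank test", data.name = "clin by group"),
              class = "htest")
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-Raphson, Breslow tie handling)
#' via [survival::coxph]; standard errors from the inverse observed
#' information. Non-convergence or monotone likelihood (perfect separation)
#' is reported through `converged = FALSE` with the last-iterate
#' coefficients, not an error.
#'
#' @param clin clinical `data.frame(sample_id, time, event)`.
#' @param covariates numeric matrix or data.frame, rows aligned to
#'   `clin$sample_id` (rownames matched when present).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list of class `"CoxFit"`: `coefficients`, `se`, `z`, `p`,
#'   `hazard_ratio`, `riskScore` (named per sample), `scoreTest` (score chi2),
#'   `converged`, `fit` (the underlying `coxph` object).
#' @export
coxFit <- function(clin, covariates, ties = c("breslow", "efron")) {
    ties <- match.arg(ties)
    clin <- .surv_df(clin)
    X <- as.matrix(covariates)
    if (!is.null(rownames(X))) X <- X[clin$sample_id, , drop = FALSE]
    if (nrow(X) != nrow(clin))
        stop("covariates must have one row per clinical sample", call. = FALSE)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (sum(clin$event) < ncol(X) + 1)
        warning("fewer events than covariates + 1; estimates are unstable")
    df <- data.frame(time = clin$time, event = clin$event, X,
                     check.names = FALSE)
    fml <- stats::as.formula(paste("Surv(time, event) ~",
                                   paste(sprintf("`%s`", colnames(X)),
                                         collapse = " + ")))
    conv <- TRUE
    fit <- withCallingHandlers(
        coxph(fml, data = df, ties = ties,
              control = coxph.control(eps = 1e-9, iter.max = 50)),
        warning = function(w) {
            if (grepl("converge|infinite|singular|beta may be infinite",
                      conditionMessage(w))) {
                conv <<- FALSE
                invokeRestart("muffleWarning")
            }
        })
    beta <- stats::coef(fit)
    if (anyNA(beta)) conv <- FALSE
    se <- sqrt(diag(fit$var))
    z <- beta / se
    score <- drop(X %*% ifelse(is.na(beta), 0, beta))
    structure(list(coefficients = beta, se = se, z = z,
                   p = 2 * stats::pnorm(-abs(z)),
                   hazard_ratio = exp(beta),
                   riskScore = stats::setNames(score, clin$sample_id),
                   scoreTest = unname(fit$score),
                   converged = conv, fit = fit),
              class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
    cat(sprintf("Cox PH fit (%s)\n",
                if (x$converged) "converged" else "NOT converged"))
    print(data.frame(beta = x$coefficients, se = x$se, z = x$z, p = x$p,
                     HR = x$hazard_ratio))
    invisible(x)
}

# standardized log2(normalized + 1) expression of one gene across samples
.module_covariate <- function(em, geneId, sampleIds) {
    nm <- if (isNormalized(em)) em else normalizeCounts(em)
    v <- exprValues(nm)
    if (!geneId %in% rownames(v))
        stop("module member '", geneId, "' missing from the ",
             compartment(em), " matrix", call. = FALSE)
    x <- log2(v[geneId, sampleIds] + 1)
    if (stats::sd(x) == 0) x - mean(x) else as.numeric(scale(x))
}

#' Multivariate Cox risk score for one ceRNA module
#'
#' Fits a multivariate Cox model on the three module members' standardized
#' `log2(normalized + 1)` expression, computes the per-sample risk score
#' `beta' x`, splits the cohort at the median score (ties, including the
#' median itself, go to the low-risk group) and runs Kaplan-Meier plus
#' log-rank on the split.
#'
#' @param clin clinical table.
#' @param module named character vector or list with `lncrna`, `mirna`,
#'   `mrna` gene ids.
#' @param exprList list with elements `mRNA`, `lncRNA`, `miRNA` of
#'   [ExpressionMatrix-class] (raw or normalized).
#' @return list of class `"ModuleRiskFit"`: `cox` ([coxFit()] result),
#'   `riskScore`, `riskGroup` (`high`/`low` per sample), `km`
#'   ([survival::survfit]), `logrank` (`htest`).
#' @export
moduleRiskScore <- function(clin, module, exprList) {
    clin <- .surv_df(clin)
    ids <- clin$sample_id
    X <- cbind(
        lncrna = .module_covariate(exprList$lncRNA, module[["lncrna"]], ids),
        mirna = .module_covariate(exprList$miRNA, module[["mirna"]], ids),
        mrna = .module_covariate(exprList$mRNA, module[["mrna"]], ids))
    rownames(X) <- ids
    cx <- coxFit(clin, X)
    score <- cx$riskScore
    grp <- ifelse(score <= stats::median(score), "low", "high")
    names(grp) <- ids
    lr <- if (length(unique(grp)) == 2) logrankTest(clin, grp) else NULL
    km <- if (length(unique(grp)) >= 1) kmFit(clin, grp) else NULL
    structure(list(module = module, cox = cx, riskScore = score,
                   riskGroup = grp, km = km, logrank = lr),
              class = "ModuleRiskFit")
}

#' @export
print.ModuleRiskFit <- function(x, ...) {
    cat(sprintf("ceRNA module %s | %s | %s\n", x$module[["lncrna"]],
                x$module[["mirna"]], x$module[["mrna"]]))
    print(x$cox)
    if (!is.null(x$logrank))
        cat(sprintf("median-split log-rank: chisq = %.3f, p = %.3g\n",
                    x$logrank$statistic, x$logrank$p.value))
    invisible(x)
}

# overall KM survival probability at time t (right-continuous)
.km_at <- function(time, event, t) {
    fit <- survfit(Surv(time, event) ~ 1)
    s <- summary(fit, times = t, extend = TRUE)$surv
    if (!length(s)) 1 else s
}

#' Time-dependent ROC and AUC for a censored survival marker
#'
#' Cumulative/dynamic ROC at horizon `tStar`: cases are subjects with an
#' event by `tStar`, controls those event-free at `tStar`, estimated under
#' censoring with the Kaplan-Meier method of Heagerty, Lumley and Pepe:
#' \deqn{Sens(c) = \frac{(1 - S(t^* | M > c)) P(M > c)}{1 - S(t^*)}, \quad
#'       Spec(c) = \frac{S(t^* | M \le c) P(M \le c)}{S(t^*)}}
#' over the marker's observed cutoffs; AUC by the trapezoid rule. With no
#' censoring this reduces exactly to the classical empirical ROC of the
#' binary outcome "event by `tStar`".
#'
#' @param clin clinical table.
#' @param marker named (or clin-aligned) numeric per-sample score; higher
#'   values mean higher risk.
#' @param tStar evaluation time, within the observed time range with at
#'   least one event at or before it and overall `S(tStar) > 0`.
#' @return list of class `"TimeROC"`: `tStar`, `auc`, `roc`
#'   (`data.frame(cutoff, sens, spec)`).
#' @export
timeDependentRoc <- function(clin, marker, tStar) {
    clin <- .surv_df(clin)
    m <- if (!is.null(names(marker))) marker[clin$sample_id] else marker
    if (anyNA(m)) stop("marker missing for some samples", call. = FALSE)
    if (tStar <= 0 || tStar > max(clin$time))
        stop("tStar must lie within the observed time range", call. = FALSE)
    if (!any(clin$time <= tStar & clin$event == 1))
        stop("no events at or before tStar", call. = FALSE)
    S0 <- .km_at(clin$time, clin$event, tStar)
    if (S0 <= 0) stop("overall survival at tStar is 0", call. = FALSE)
    if (S0 >= 1) stop("no event probability mass by tStar", call. = FALSE)

    cuts <- sort(unique(m))
    sens <- spec <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
        pos <- m > cuts[i]
        pPos <- mean(pos)
        S1 <- if (any(pos)) .km_at(clin$time[pos], clin$event[pos], tStar) else 1
        S2 <- if (any(!pos)) .km_at(clin$time[!pos], clin$event[!pos], tStar) else 1
        sens[i] <- (1 - S1) * pPos / (1 - S0)
        spec[i] <- S2 * (1 - pPos) / S0
    }
    sens <- pmin(pmax(sens, 0), 1)
    spec <- pmin(pmax(spec, 0), 1)
    # snap away float jitter so equal coordinates sort as one staircase step
    fpr <- round(c(1, 1 - spec, 0), 12)
    tpr <- round(c(1, sens, 0), 12)
    ord <- order(fpr, tpr)
    fpr <- fpr[ord]; tpr <- tpr[ord]
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    structure(list(tStar = tStar, auc = auc,
                   roc = data.frame(cutoff = cuts, sens = sens, spec = spec)),
              class = "TimeROC")
}

#' @export
print.TimeROC <- function(x, ...) {
    cat(sprintf("time-dependent ROC at t* = %g: AUC = %.3f (%d cutoffs)\n",
                x$tStar, x$auc, nrow(x$roc)))
    invisible(x)
}
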