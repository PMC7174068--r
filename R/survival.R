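#' Assign samples to TMB quartiles
#'
#' Cut points are the empirical 25/50/75 percentiles (linear interpolation
#' between order statistics, `stats::quantile` type 7), computed over the
#' whole cohort (`pan_cohort`) or separately within each tumor type
#' (`intra_tumor_type`). A sample goes to Q1 if its TMB is <= the 25th
#' percentile, Q2 if <= the median, Q3 if <= the 75th percentile, and Q4
#' otherwise, so Q4 is the highest-TMB quarter and ties at a cut fall in the
#' lower group. Strata with fewer than `min_stratum` samples, or with a
#' single distinct TMB value, are skipped with a warning.
#'
#' @param tmb_by_sample Tibble with `sample_id` and `tmb`.
#' @param clinical Tibble with `sample_id`, `tumor_type`, `os_days`,
#'   `event`; only used (and required) in `intra_tumor_type` mode, where it
#'   supplies the stratum of each sample.
#' @param mode `"pan_cohort"` or `"intra_tumor_type"`.
#' @param min_stratum Minimum samples per stratum (default 8).
#' @return A `quartile_assignment`: `mode`, `cuts` (tibble of stratum,
#'   `c25`, `c50`, `c75`), `groups` (tibble of `sample_id`, `stratum`,
#'   `tmb`, `quartile`), `quantile_type = 7`.
#' @export
assign_quartiles <- function(tmb_by_sample,
                             clinical = NULL,
                             mode = c("pan_cohort", "intra_tumor_type"),
                             min_stratum = 8) {
  mode <- match.arg(mode)
  d <- tibble::as_tibble(tmb_by_sample)[, c("sample_id", "tmb")]
  stopifnot(!anyNA(d$tmb))
  if (mode == "intra_tumor_type") {
    if (is.null(clinical)) stop("intra_tumor_type mode needs a clinical table")
    d <- dplyr::inner_join(d, tibble::as_tibble(clinical)[, c("sample_id", "tumor_type")],
                           by = "sample_id")
    d$stratum <- d$tumor_type
  } else {
    d$stratum <- "all"
  }
  cuts <- list(); groups <- list()
  for (s in unique(d$stratum)) {
    ds <- d[d$stratum == s, , drop = FALSE]
    if (nrow(ds) < min_stratum) {
      warning("stratum '", s, "' has ", nrow(ds), " samples (< ", min_stratum,
              "); skipped")
      next
    }
    if (length(unique(ds$tmb)) == 1L) {
      warning("stratum '", s, "' has a single distinct TMB value; skipped")
      next
    }
    q <- stats::quantile(ds$tmb, probs = c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    lab <- ifelse(ds$tmb <= q[1], "Q1",
                  ifelse(ds$tmb <= q[2], "Q2",
                         ifelse(ds$tmb <= q[3], "Q3", "Q4")))
    cuts[[s]] <- tibble::tibble(stratum = s, c25 = q[1], c50 = q[2], c75 = q[3])
    groups[[s]] <- tibble::tibble(sample_id = ds$sample_id, stratum = s,
                                  tmb = ds$tmb,
                                  quartile = factor(lab, levels = paste0("Q", 1:4)))
  }
  if (!length(groups)) stop("no stratum could be quartiled")
  structure(list(mode = mode,
                 cuts = dplyr::bind_rows(cuts),
                 groups = dplyr::bind_rows(groups),
                 quantile_type = 7L),
            class = "quartile_assignment")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, overall or per group.
#'
#' @param clinical Tibble with `os_days` and `event` (1 = death observed,
#'   0 = censored).
#' @param group Optional factor/character vector (same length as rows of
#'   `clinical`) to stratify by.
#' @return Tidy tibble: `group` (if given), `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_curve <- function(clinical, group = NULL) {
  stopifnot(nrow(clinical) >= 1)
  su <- survival::Surv(clinical$os_days, clinical$event)
  if (is.null(group)) {
    fit <- survival::survfit(su ~ 1)
    tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv)
  } else {
    df <- data.frame(g = factor(group))
    fit <- survival::survfit(su ~ g, data = df)
    strata <- rep(names(fit$strata), fit$strata)
    tibble::tibble(group = sub("^g=", "", strata), time = fit$time,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   survival = fit$surv)
  }
}

#' Cox proportional-hazards quartile contrasts
#'
#' Fits, within each stratum of a quartile assignment, a Cox model with the
#' TMB quartile as a categorical covariate and reports the hazard ratio of
#' each quartile against the reference with a 95% Wald confidence interval
#' from the observed information. Ties are handled with the Efron
#' approximation by default. A quartile with no events yields a monotone
#' partial likelihood; the contrast is still reported, flagged as unstable,
#' with the (infinite or near-infinite) bounds the model produces.
#'
#' @param clinical Tibble with `sample_id`, `os_days`, `event`.
#' @param qa A [assign_quartiles()] result.
#' @param reference Reference quartile, default `"Q1"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Tibble: `stratum`, `contrast`, `hr`, `ci_low`, `ci_high`,
#'   `n_group`, `n_events`, `ties_method`, `unstable`.
#' @export
cox_quartile_hr <- function(clinical, qa, reference = "Q1",
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(qa, "quartile_assignment"),
            reference %in% paste0("Q", 1:4))
  cl <- tibble::as_tibble(clinical)[, c("sample_id", "os_days", "event")]
  d <- dplyr::inner_join(qa$groups, cl, by = "sample_id")
  if (!nrow(d)) stop("no samples shared between quartile assignment and clinical table")
  out <- list()
  for (s in unique(d$stratum)) {
    ds <- d[d$stratum == s, , drop = FALSE]
    ds$quartile <- droplevels(factor(ds$quartile))
    if (!(reference %in% levels(ds$quartile))) {
      warning("stratum '", s, "': reference group '", reference,
              "' is empty; skipped")
      next
    }
    ds$quartile <- stats::relevel(ds$quartile, ref = reference)
    if (sum(ds$event[ds$quartile == reference]) < 1) {
      warning("stratum '", s, "': reference group has no events")
    }
    fit <- suppressWarnings(survival::coxph(
      survival::Surv(os_days, event) ~ quartile, data = ds, ties = ties))
    sm <- suppressWarnings(summary(fit))
    co <- sm$conf.int  # exp(coef), exp(-coef), lower .95, upper .95
    terms <- sub("^quartile", "", rownames(co))
    for (i in seq_along(terms)) {
      g <- terms[i]
      hr <- co[i, "exp(coef)"]
      lo <- co[i, "lower .95"]; hi <- co[i, "upper .95"]
      unstable <- !is.finite(lo) || !is.finite(hi) || hi > 1e6 || lo < 1e-6
      out[[length(out) + 1L]] <- tibble::tibble(
        stratum = s,
        contrast = paste(g, "vs", reference),
        hr = hr, ci_low = lo, ci_high = hi,
        n_group = sum(ds$quartile == g),
        n_events = sum(ds$event[ds$quartile == g]),
        ties_method = ties,
        unstable = unstable)
    }
  }
  dplyr::bind_rows(out)
}

#' Per-method survival report
#'
#' For every TMB counting method in a cohort matrix: assign quartiles
#' (pan-cohort or within tumor type), fit the quartile Cox model, and
#' tabulate Kaplan-Meier curves per quartile. TMB and clinical tables are
#' joined on `sample_id` (inner join); mismatches are reported with a
#' message, and an empty intersection is an error. A method with a constant
#' TMB across the cohort is skipped with a warning.
#'
#' @param m A [tmb_matrix()].
#' @param clinical Tibble with `sample_id`, `tumor_type`, `os_days`,
#'   `event`.
#' @param mode Quartile mode, `"pan_cohort"` or `"intra_tumor_type"`.
#' @param reference Reference quartile for hazard ratios.
#' @param ties Tie handling for the Cox partial likelihood.
#' @return List with `hr` (tibble: method + [cox_quartile_hr()] columns),
#'   `km` (tibble: method, stratum, quartile KM tables), and `cuts` (tibble
#'   of quartile cut points per method and stratum).
#' @export
survival_report <- function(m, clinical, mode = c("pan_cohort", "intra_tumor_type"),
                            reference = "Q1", ties = c("efron", "breslow")) {
  mode <- match.arg(mode); ties <- match.arg(ties)
  cl <- tibble::as_tibble(clinical)
  keep <- stats::complete.cases(cl[, c("sample_id", "os_days", "event")])
  if (any(!keep)) {
    message(sum(!keep), " clinical record(s) with missing fields dropped")
    cl <- cl[keep, , drop = FALSE]
  }
  ml <- tibble::as_tibble(m)
  shared <- intersect(unique(ml$sample_id), cl$sample_id)
  if (!length(shared)) stop("empty join: no samples shared between TMB matrix and clinical table")
  n_miss <- length(unique(ml$sample_id)) - length(shared)
  if (n_miss > 0) message(n_miss, " TMB sample(s) missing from the clinical table")
  if (length(shared) < 8) stop("fewer than 8 shared samples; survival analysis not meaningful")
  hr <- list(); km <- list(); cuts <- list()
  for (lab in unique(ml$method_label)) {
    tv <- ml[ml$method_label == lab & ml$sample_id %in% shared,
             c("sample_id", "tmb")]
    if (length(unique(tv$tmb)) == 1L) {
      warning("method '", lab, "' has constant TMB; skipped")
      next
    }
    qa <- assign_quartiles(tv, clinical = cl, mode = mode)
    h <- cox_quartile_hr(cl, qa, reference = reference, ties = ties)
    hr[[lab]] <- dplyr::bind_cols(tibble::tibble(method = lab), h)
    cuts[[lab]] <- dplyr::bind_cols(tibble::tibble(method = lab), qa$cuts)
    dk <- dplyr::inner_join(qa$groups, cl[, c("sample_id", "os_days", "event")],
                            by = "sample_id")
    kms <- lapply(split(dk, dk$stratum), function(ds) {
      k <- km_curve(ds, group = ds$quartile)
      dplyr::bind_cols(tibble::tibble(method = lab, stratum = ds$stratum[1]), k)
    })
    km[[lab]] <- dplyr::bind_rows(kms)
  }
  if (!length(hr)) stop("no method could be analysed")
  list(hr = dplyr::bind_rows(hr), km = dplyr::bind_rows(km),
       cuts = dplyr::bind_rows(cuts))
}
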