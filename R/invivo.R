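# Synthetic in-vivo cohort: control + four irradiated groups (40/80/120/160
# kVp, 3 Gy surface dose, 5 mice each), exponential tumor growth suppressed
# in proportion to the normalized tumor average absorbed dose, lognormal
# measurement noise, caliper volume formula and tumor-growth-inhibition
# rate, plus the AAD-TGI correlation of the validation pipeline.

#' Caliper tumor volume
#'
#' Computes `0.5 * L * W` as used in the animal protocol. The conventional
#' ellipsoid-style variant `0.5 * L * W^2` is available behind
#' `formula = "lw2"`.
#'
#' @param L,W Tumor length and width, mm (`L >= W > 0`).
#' @param formula `"lw"` (as used here) or `"lw2"`.
#' @return Volume, mm^3.
#' @export
tumor_volume <- function(L, W, formula = c("lw", "lw2")) {
  formula <- match.arg(formula)
  stopifnot(all(W > 0), all(L >= W))
  if (formula == "lw") 0.5 * L * W else 0.5 * L * W^2
}

#' Tumor growth inhibition rate
#'
#' TGI = (1 - (V_TE - V_TS) / (V_NE - V_NS)) * 100, in percent; may exceed
#' 100 (tumor regression) or be negative (faster-than-control growth).
#'
#' @param v_ts,v_te Initial and final treated-group volumes, mm^3.
#' @param v_ns,v_ne Initial and final control-group volumes, mm^3.
#' @return TGI in percent.
#' @export
tgi <- function(v_ts, v_te, v_ns, v_ne) {
  stopifnot(all(c(v_ts, v_te, v_ns, v_ne) > 0))
  if (any(v_ne == v_ns)) stop("control group shows zero growth")
  (1 - (v_te - v_ts) / (v_ne - v_ns)) * 100
}

#' Cohort design for the synthetic experiment
#'
#' Defaults mirror the study arms: a control group plus irradiation at
#' 40/80/120/160 kVp, five mice per group, starting volumes uniform in
#' 70-125 mm^3, 14 days of exponential growth at 0.15/day in controls,
#' treated growth rate reduced by `dose_effect_slope` times the normalized
#' AAD (clipped at zero), and multiplicative lognormal measurement noise.
#'
#' @param groups Group labels; `"control"` plus kVp values.
#' @param n_per_group Mice per group.
#' @param start_volume_range Initial-volume range, mm^3.
#' @param control_growth_rate Exponential growth rate, per day.
#' @param days Follow-up, days.
#' @param dose_effect_slope Fractional growth-rate suppression per unit
#'   normalized AAD (`s`); `s = 1` with AAD_norm 1 freezes growth.
#' @param noise_cv Lognormal coefficient of variation of measured volumes.
#' @param seed RNG seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c("control", "40", "80", "120", "160"),
                          n_per_group = 5, start_volume_range = c(70, 125),
                          control_growth_rate = 0.15, days = 14,
                          dose_effect_slope = 0.8, noise_cv = 0.15,
                          seed = 1L) {
  stopifnot(n_per_group >= 1, control_growth_rate >= 0, noise_cv >= 0,
            days > 0, "control" %in% groups,
            diff(start_volume_range) >= 0, all(start_volume_range > 0))
  structure(list(groups = groups, n_per_group = n_per_group,
                 start_volume_range = start_volume_range,
                 control_growth_rate = control_growth_rate, days = days,
                 dose_effect_slope = dose_effect_slope,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a synthetic tumor-growth cohort
#'
#' Per mouse: V_start uniform in the design range; controls grow as
#' V_start exp(g days); treated growth rate is g (1 - s AAD_norm), clipped
#' at zero; measured volumes get multiplicative lognormal noise with the
#' design CV. Group volumes are averaged before the TGI formula (group-mean
#' convention); per-mouse TGI with averaging afterwards is available via
#' `tgi_by = "mouse"`.
#'
#' @param design A [cohort_design()].
#' @param aad_by_group Named vector of normalized AAD in `[0, 1]` for every
#'   non-control group.
#' @param tgi_by `"group"` (default) or `"mouse"`.
#' @return An object of class `xpdt_cohort`: list with `mice` (per-mouse
#'   data frame) and `groups` (per-group outcomes incl. `tgi_percent`).
#' @export
#' @examples
#' d <- cohort_design(noise_cv = 0, seed = 7)
#' co <- simulate_cohort(d, c("40" = 0.6, "80" = 1, "120" = 0.8,
#'                            "160" = 0.7))
#' co$groups
simulate_cohort <- function(design, aad_by_group,
                            tgi_by = c("group", "mouse")) {
  stopifnot(inherits(design, "cohort_design"))
  tgi_by <- match.arg(tgi_by)
  treated <- setdiff(design$groups, "control")
  missing <- setdiff(treated, names(aad_by_group))
  if (length(missing)) {
    stop("missing AAD for group(s): ", paste(missing, collapse = ", "))
  }
  if (any(aad_by_group < 0 | aad_by_group > 1)) {
    stop("normalized AAD must lie in [0, 1]")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  n <- design$n_per_group
  # matched starting volumes across groups (common random numbers), so the
  # noise-free cohort hits the closed-form TGI limits exactly
  v0_base <- runif(n, design$start_volume_range[1],
                   design$start_volume_range[2])
  mice <- do.call(rbind, lapply(design$groups, function(gname) {
    v0 <- v0_base
    rate <- if (gname == "control") design$control_growth_rate else
      max(0, design$control_growth_rate *
            (1 - design$dose_effect_slope * aad_by_group[[gname]]))
    v1 <- v0 * exp(rate * design$days)
    noise0 <- rlnorm(n, -sdlog^2 / 2, sdlog)
    noise1 <- rlnorm(n, -sdlog^2 / 2, sdlog)
    data.frame(group = gname, mouse = seq_len(n),
               v_start = v0 * noise0, v_end = v1 * noise1)
  }))
  gsum <- do.call(rbind, lapply(split(mice, mice$group), function(d) {
    data.frame(group = d$group[1], v_start_mean = mean(d$v_start),
               v_end_mean = mean(d$v_end))
  }))
  gsum <- gsum[match(design$groups, gsum$group), ]
  ctrl <- gsum[gsum$group == "control", ]
  gsum$tgi_percent <- NA_real_
  for (g in treated) {
    i <- which(gsum$group == g)
    if (tgi_by == "group") {
      gsum$tgi_percent[i] <- tgi(gsum$v_start_mean[i], gsum$v_end_mean[i],
                                 ctrl$v_start_mean, ctrl$v_end_mean)
    } else {
      dm <- mice[mice$group == g, ]
      cm <- mice[mice$group == "control", ]
      gsum$tgi_percent[i] <- mean(tgi(dm$v_start, dm$v_end,
                                      mean(cm$v_start), mean(cm$v_end)))
    }
  }
  rownames(gsum) <- NULL
  structure(list(mice = mice, groups = gsum, design = design,
                 aad_by_group = aad_by_group), class = "xpdt_cohort")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.xpdt_cohort <- function(x, ...) {
  cat(sprintf("<xpdt_cohort> %d groups x %d mice, %g days\n",
              length(x$design$groups), x$design$n_per_group, x$design$days))
  print(x$groups)
  invisible(x)
}

#' Recover the dose-effect slope from a noise-free cohort
#'
#' Linearizes the exponential growth model: per group, the realized growth
#' rate is log(V_end_mean / V_start_mean) / days = g (1 - s AAD_norm), so
#' regressing the realized rate on AAD_norm recovers `s` exactly in the
#' zero-noise limit (group means factor out the random starting volumes).
#'
#' @param cohort An [simulate_cohort()] result.
#' @return Estimated slope `s`.
#' @export
recover_effect_slope <- function(cohort) {
  stopifnot(inherits(cohort, "xpdt_cohort"))
  g <- cohort$groups
  treated <- g[g$group != "control", ]
  a <- cohort$aad_by_group[treated$group]
  rate <- log(treated$v_end_mean / treated$v_start_mean) /
    cohort$design$days
  fit <- lm(rate ~ a)
  -coef(fit)[["a"]] / cohort$design$control_growth_rate
}

#' Pearson correlation with validation
#'
#' Thin wrapper over the product-moment correlation with the input checks
#' the pipeline relies on (equal length >= 3, non-degenerate variances).
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with at least 3 points")
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in correlation input")
  cor(x, y, method = "pearson")
}

#' Correlate simulated AAD with synthetic TGI
#'
#' Pearson correlation between the per-group TGI of a cohort and the
#' model's AAD at the matching tube potentials.
#'
#' @param aad_by_kvp Named vector: AAD (any consistent scale) per kVp
#'   label covering every treated group.
#' @param cohort An [simulate_cohort()] result.
#' @return Pearson correlation coefficient.
#' @export
correlate_aad_tgi <- function(aad_by_kvp, cohort) {
  stopifnot(inherits(cohort, "xpdt_cohort"))
  g <- cohort$groups
  treated <- g[g$group != "control", ]
  missing <- setdiff(treated$group, names(aad_by_kvp))
  if (length(missing)) {
    stop("AAD not available at kVp: ", paste(missing, collapse = ", "))
  }
  pearson_r(unname(aad_by_kvp[treated$group]), treated$tgi_percent)
}
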