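#' Checkerboard dose matrix of % viability
#'
#' A `length(doses1) x length(doses2)` grid of viability values aligned to
#' two ascending dose vectors whose first entries are 0, so cell (1, 1) in
#' R indexing is the untreated reference. Missing cells are `NA`.
#'
#' @param values numeric matrix of % viability (`NA` allowed).
#' @param doses1,doses2 ascending dose vectors (uM) with first entry 0;
#'   rows follow drug 1, columns drug 2.
#' @param pair_id,cell_line,day,replicate identifiers carried through to
#'   results.
#' @param provenance `"measured"` or `"predicted"`.
#' @return An object of class `dose_matrix`.
#' @export
dose_matrix <- function(values, doses1, doses2, pair_id = NA, cell_line = NA,
                        day = NA, replicate = NA, provenance = "measured") {
  values <- as.matrix(values)
  if (nrow(values) != length(doses1) || ncol(values) != length(doses2)) {
    stopf("values must be %d x %d to match the dose vectors",
          length(doses1), length(doses2))
  }
  if (doses1[1] != 0 || doses2[1] != 0) stopf("dose vectors must start at 0")
  if (is.unsorted(doses1) || is.unsorted(doses2)) {
    stopf("dose vectors must be ascending")
  }
  if (any(values < 0, na.rm = TRUE)) stopf("viability values must be >= 0")
  structure(list(values = values, doses1 = doses1, doses2 = doses2,
                 pair_id = pair_id, cell_line = cell_line, day = day,
                 replicate = replicate, provenance = provenance),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("<dose_matrix> pair %s / %s / day %s (%s), %d NA\n",
              x$pair_id, x$cell_line, x$day, x$provenance,
              sum(is.na(x$values))))
  print(round(x$values, 1))
  invisible(x)
}

same_layout <- function(m1, m2) {
  isTRUE(all.equal(m1$doses1, m2$doses1)) &&
    isTRUE(all.equal(m1$doses2, m2$doses2))
}

#' Merge two replicate matrices
#'
#' Cellwise mean where both replicates have a value, the single value where
#' only one does, `NA` where both are missing.
#'
#' @param m1,m2 [dose_matrix()] replicates sharing dose vectors and
#'   identifiers.
#' @return A merged [dose_matrix()].
#' @export
merge_replicates <- function(m1, m2) {
  if (!same_layout(m1, m2)) stopf("replicate dose vectors do not match")
  v1 <- m1$values; v2 <- m2$values
  v <- ifelse(is.na(v1), v2, ifelse(is.na(v2), v1, (v1 + v2) / 2))
  out <- m1
  out$values <- v
  out$replicate <- NA
  out
}

is_mono_cell <- function(m) {
  mono <- matrix(FALSE, nrow(m$values), ncol(m$values))
  mono[1, ] <- TRUE
  mono[, 1] <- TRUE
  mono
}

#' Apply the replicate missing-data rules
#'
#' A matrix with any missing monotherapy cell (first row or first column,
#' including the untreated well) is excluded outright. In surviving
#' matrices, missing interior (combination) cells are imputed with 100%
#' viability. Returns the 0, 1 or 2 usable matrices; when one replicate is
#' excluded, synergy is computed from the complete one alone.
#'
#' @param m1 a [dose_matrix()].
#' @param m2 optional second replicate.
#' @return List of usable matrices (possibly empty), with attributes
#'   `n_excluded` and `n_imputed`.
#' @export
apply_missing_rules <- function(m1, m2 = NULL) {
  mats <- Filter(Negate(is.null), list(m1, m2))
  out <- list()
  n_excluded <- 0L
  n_imputed <- 0L
  for (m in mats) {
    mono <- is_mono_cell(m)
    if (any(is.na(m$values[mono]))) {
      n_excluded <- n_excluded + 1L
      next
    }
    interior_na <- is.na(m$values) & !mono
    if (any(interior_na)) {
      m$values[interior_na] <- 100
      n_imputed <- n_imputed + sum(interior_na)
    }
    out <- c(out, list(m))
  }
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Four-parameter log-logistic (Hill) monotherapy curve
#'
#' Viability model \eqn{V(d) = e_{max} + (e_0 - e_{max}) / (1 +
#' (d/ec_{50})^{slope})}, fitted by bounded Levenberg-Marquardt least
#' squares with multi-start over log-spaced `ec50` values. Bounds: `e0` in
#' 80..120, `emax` in 0..100, `ec50` within (min nonzero dose)/100 to
#' (max dose) x 100, `slope` in 0.2..10.
#'
#' Degenerate inputs are handled rather than rejected: all-equal
#' viabilities give a flat fit (`e0 = emax = mean`, flagged `"flat"`);
#' viability that clearly increases with dose is fitted anyway but flagged
#' `"poor_fit"`.
#'
#' @param doses ascending doses (uM) including 0, `>= 4` points.
#' @param viabilities % viability at each dose.
#' @return An object of class `hill_fit`: `e0`, `emax`, `ec50`, `slope`,
#'   `flag` (`""`, `"flat"` or `"poor_fit"`), `rss`.
#' @export
fit_monotherapy <- function(doses, viabilities) {
  keep <- is.finite(viabilities)
  doses <- doses[keep]; viabilities <- viabilities[keep]
  if (length(doses) < 4) stopf("need >= 4 dose points, got %d", length(doses))
  if (!any(doses == 0)) stopf("doses must include 0")

  if (diff(range(viabilities)) < 1e-9) {
    return(structure(list(e0 = mean(viabilities), emax = mean(viabilities),
                          ec50 = max(doses[doses > 0]), slope = 1,
                          flag = "flat", rss = 0), class = "hill_fit"))
  }

  dmin <- min(doses[doses > 0]); dmax <- max(doses)
  lower <- c(e0 = 80, emax = 0, lec50 = log10(dmin / 100), slope = 0.2)
  upper <- c(e0 = 120, emax = 100, lec50 = log10(dmax * 100), slope = 10)
  model <- function(p, d) {
    p["emax"] + (p["e0"] - p["emax"]) /
      (1 + ifelse(d <= 0, 0, (d / 10^p["lec50"])^p["slope"]))
  }
  resid_fn <- function(p) model(p, doses) - viabilities

  e0_start <- min(max(viabilities[doses == 0][1], 80), 120)
  emax_start <- min(max(min(viabilities), 0), 100)
  best <- NULL
  for (lec50 in log10(exp(seq(log(dmin / 3), log(dmax * 3), length.out = 7)))) {
    start <- c(e0 = e0_start, emax = emax_start, lec50 = lec50, slope = 1)
    fit <- tryCatch(
      minpack.lm::nls.lm(start, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stopf("monotherapy fit failed to converge from any start")

  # flag clear dose-dependent increase (biologically implausible direction)
  flag <- ""
  nz <- doses > 0
  if (sum(nz) >= 2) {
    trend <- stats::coef(stats::lm(viabilities[nz] ~ log10(doses[nz])))[2]
    if (is.finite(trend) && trend > 5) flag <- "poor_fit"
  }
  p <- best$par
  structure(list(e0 = unname(p["e0"]), emax = unname(p["emax"]),
                 ec50 = unname(10^p["lec50"]), slope = unname(p["slope"]),
                 flag = flag, rss = best$rss),
            class = "hill_fit")
}

#' Evaluate a fitted Hill curve
#'
#' @param h a [fit_monotherapy()] fit (or any list with `e0`, `emax`,
#'   `ec50`, `slope`).
#' @param d doses (uM), vectorized; `d = 0` returns `e0`.
#' @return % viability.
#' @export
hill_viability <- function(h, d) {
  ifelse(d <= 0, h$e0,
         h$emax + (h$e0 - h$emax) / (1 + (d / h$ec50)^h$slope))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> e0=%.1f emax=%.1f ec50=%.4g slope=%.2f%s\n",
              x$e0, x$emax, x$ec50, x$slope,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Bliss independence reference surface
#'
#' \eqn{V_{ref}(d_1, d_2) = V_A(d_1) \cdot V_B(d_2) / 100} from the fitted
#' monotherapy curves (viability scale).
#'
#' @param hA,hB fitted [fit_monotherapy()] curves for drug 1 (rows) and
#'   drug 2 (columns).
#' @param doses1,doses2 ascending dose vectors with leading 0.
#' @return Reference matrix of % viability.
#' @export
bliss_reference <- function(hA, hB, doses1, doses2) {
  outer(hill_viability(hA, doses1), hill_viability(hB, doses2)) / 100
}

#' Highest-single-agent reference surface
#'
#' \eqn{V_{ref}(d_1, d_2) = \min(V_A(d_1), V_B(d_2))}: the better of the
#' two monotherapies at the component doses.
#'
#' @inheritParams bliss_reference
#' @return Reference matrix of % viability.
#' @export
hsa_reference <- function(hA, hB, doses1, doses2) {
  outer(hill_viability(hA, doses1), hill_viability(hB, doses2), pmin)
}

# Inverse Hill dose D(V); V must satisfy emax < V < e0.
inverse_hill_dose <- function(h, v) {
  h$ec50 * ((h$e0 - v) / (v - h$emax))^(1 / h$slope)
}

is_flat_curve <- function(h, tol = 1e-6) (h$e0 - h$emax) <= tol

#' Loewe additivity reference surface
#'
#' For each cell the reference viability `V` solves the dose-equivalence
#' relation \eqn{d_1 / D_A(V) + d_2 / D_B(V) = 1}, where \eqn{D_X(V)} is
#' the inverse dose of the fitted monotherapy curve. Solved by bisection on
#' `V`; when a viability level is unreachable for one drug (below its
#' `emax`) that drug's term is 0 — the drug cannot contribute at that
#' effect level. A drug combined with itself is exactly additive under this
#' reference (sham combination).
#'
#' @inheritParams bliss_reference
#' @param tol convergence tolerance on the interaction sum.
#' @return Reference matrix of % viability. If both curves are flat the
#'   untreated plane `e0` is returned with attribute `flagged = TRUE`.
#' @export
loewe_reference <- function(hA, hB, doses1, doses2, tol = 1e-9) {
  n1 <- length(doses1); n2 <- length(doses2)
  flatA <- is_flat_curve(hA); flatB <- is_flat_curve(hB)
  if (flatA && flatB) {
    ref <- matrix(min(hA$e0, hB$e0), n1, n2)
    attr(ref, "flagged") <- TRUE
    return(ref)
  }
  hi_cap <- min(hA$e0, hB$e0)
  lo_cap <- min(if (flatA) Inf else hA$emax, if (flatB) Inf else hB$emax)
  gfun <- function(v, d1, d2) {
    s <- 0
    if (d1 > 0) {
      if (flatA || v <= hA$emax) s <- s + 0
      else if (v >= hA$e0) return(Inf)
      else s <- s + d1 / inverse_hill_dose(hA, v)
    }
    if (d2 > 0) {
      if (flatB || v <= hB$emax) s <- s + 0
      else if (v >= hB$e0) return(Inf)
      else s <- s + d2 / inverse_hill_dose(hB, v)
    }
    s - 1
  }
  ref <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    d1 <- doses1[i]; d2 <- doses2[j]
    if (d1 == 0 && d2 == 0) { ref[i, j] <- hi_cap; next }
    lo <- lo_cap + 1e-12
    hi <- hi_cap - 1e-12
    if (gfun(hi, d1, d2) <= 0) { ref[i, j] <- hi_cap; next }
    if (gfun(lo, d1, d2) >= 0) { ref[i, j] <- lo_cap; next }
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      gm <- gfun(mid, d1, d2)
      if (is.finite(gm) && abs(gm) < tol) break
      if (gm > 0) hi <- mid else lo <- mid
    }
    ref[i, j] <- mid
  }
  ref
}

#' Synergy map and score from an observed matrix and a reference surface
#'
#' `delta = reference - observed` per cell (% viability): positive values
#' mean the combination pushed viability below the additive expectation,
#' i.e. synergy. The scalar `score` is the mean of `delta` over the
#' combination wells (both doses > 0); `volume` is a log-dose-step-weighted
#' sum of the same cells.
#'
#' @param observed a [dose_matrix()].
#' @param reference reference matrix from [bliss_reference()],
#'   [hsa_reference()] or [loewe_reference()].
#' @param method `"LOEWE"`, `"BLISS"` or `"HSA"` tag carried to the result.
#' @return An object of class `synergy_result`: `method`, `reference`,
#'   `delta`, `score`, `volume`, `n_wells_used`, plus the matrix
#'   identifiers.
#' @export
synergy_map <- function(observed, reference, method) {
  v <- observed$values
  if (!all(dim(v) == dim(reference))) stopf("matrix shapes do not match")
  delta <- reference - v
  combo <- outer(observed$doses1 > 0, observed$doses2 > 0, `&`)
  used <- combo & !is.na(delta)
  if (!any(used)) stopf("no combination wells present; score undefined")
  # trapezoid-style weights on the log10 dose axes
  wts <- function(d) {
    nz <- d > 0
    ld <- log10(d[nz])
    w <- numeric(length(d))
    w[nz] <- if (length(ld) == 1) 1 else {
      mids <- (ld[-1] + ld[-length(ld)]) / 2
      diff(c(ld[1], mids, ld[length(ld)]))
    }
    w
  }
  w <- outer(wts(observed$doses1), wts(observed$doses2))
  w_norm <- w / mean(w[combo])
  structure(list(method = toupper(method), reference = reference,
                 delta = delta,
                 score = mean(delta[used]),
                 volume = sum((delta * w_norm)[used]) / sum(combo),
                 n_wells_used = sum(used),
                 pair_id = observed$pair_id, cell_line = observed$cell_line,
                 day = observed$day, provenance = observed$provenance),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> %s pair %s / %s / day %s: score %.2f (n=%d)\n",
              x$method, x$pair_id, x$cell_line, x$day, x$score,
              x$n_wells_used))
  invisible(x)
}

#' Compute synergy for a collection of dose matrices
#'
#' Groups matrices by (pair, cell line, day), applies the replicate
#' missing-data rules, merges surviving replicates, fits the two
#' monotherapy Hill curves on the merged matrix, and emits one
#' [synergy_map()] result per requested method. Groups whose replicates
#' are all excluded are dropped and logged in the `exclusions` attribute.
#'
#' @param mats list of [dose_matrix()] objects (1 or 2 replicates per
#'   (pair, line, day) group).
#' @param methods subset of `c("loewe", "bliss", "hsa")`.
#' @return List of `synergy_result` objects with attribute `exclusions`
#'   (data.frame of dropped groups).
#' @export
compute_all_synergy <- function(mats, methods = c("loewe", "bliss", "hsa")) {
  methods <- match.arg(tolower(methods), c("loewe", "bliss", "hsa"),
                       several.ok = TRUE)
  keys <- vapply(mats, function(m) {
    paste(m$pair_id, m$cell_line, m$day, sep = "|")
  }, "")
  results <- list()
  excl <- list()
  for (key in unique(keys)) {
    grp <- mats[keys == key]
    usable <- if (length(grp) >= 2) {
      apply_missing_rules(grp[[1]], grp[[2]])
    } else {
      apply_missing_rules(grp[[1]])
    }
    if (length(usable) == 0) {
      excl <- c(excl, list(data.frame(key = key,
                                      reason = "monotherapy_missing")))
      next
    }
    merged <- if (length(usable) == 2) {
      merge_replicates(usable[[1]], usable[[2]])
    } else {
      usable[[1]]
    }
    hA <- fit_monotherapy(merged$doses1, merged$values[, 1])
    hB <- fit_monotherapy(merged$doses2, merged$values[1, ])
    for (method in methods) {
      ref <- switch(method,
                    loewe = loewe_reference(hA, hB, merged$doses1, merged$doses2),
                    bliss = bliss_reference(hA, hB, merged$doses1, merged$doses2),
                    hsa = hsa_reference(hA, hB, merged$doses1, merged$doses2))
      results <- c(results, list(synergy_map(merged, ref, method)))
    }
  }
  attr(results, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(key = character(0), reason = character(0))
  results
}

#' Build dose matrices from a tidy viability table
#'
#' @param df data.frame with columns `pair_id`, `cell_line`, `replicate`,
#'   `day`, `row`, `col`, `dose1_uM`, `dose2_uM` and the viability column
#'   named by `value_col`. Rows flagged `missing_reference` (when a `flag`
#'   column exists) contribute `NA` cells.
#' @param value_col name of the viability column (default `"viability"`).
#' @param provenance tag carried to the matrices.
#' @return List of [dose_matrix()] objects, one per (pair, line, replicate,
#'   day).
#' @export
matrices_from_table <- function(df, value_col = "viability",
                                provenance = "predicted") {
  need <- c("pair_id", "cell_line", "replicate", "day", "row", "col",
            "dose1_uM", "dose2_uM", value_col)
  if (!all(need %in% names(df))) {
    stopf("df needs columns: %s", paste(setdiff(need, names(df)), collapse = ", "))
  }
  vals <- df[[value_col]]
  if ("flag" %in% names(df)) vals[df$flag != ""] <- NA_real_
  key <- interaction(df$pair_id, df$cell_line, df$replicate, df$day,
                     drop = TRUE)
  lapply(levels(key), function(k) {
    idx <- which(key == k)
    sub <- df[idx, ]
    doses1 <- sort(unique(sub$dose1_uM))
    doses2 <- sort(unique(sub$dose2_uM))
    m <- matrix(NA_real_, length(doses1), length(doses2))
    m[cbind(sub$row + 1L, sub$col + 1L)] <- vals[idx]
    dose_matrix(m, doses1, doses2, pair_id = sub$pair_id[1],
                cell_line = sub$cell_line[1], day = sub$day[1],
                replicate = sub$replicate[1], provenance = provenance)
  })
}
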