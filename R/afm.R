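#' Load a force-distance curve from TSV
#'
#' Per-curve two-column TSV (piezo position in m, deflection in V) with a
#' '#'-prefixed metadata header carrying `k_spring` (N/m), `sensitivity`
#' (m/V), `R_tip` (m) and `nu`. Deflection is converted to meters via the
#' sensitivity.
#'
#' @param path file path.
#' @return a [ForceCurve-class].
#' @export
loadForceCurve <- function(path) {
  if (!file.exists(path)) stop("force-curve file not found: ", path)
  lines <- readLines(path)
  headerLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in headerLines) {
    kv <- strsplit(sub("^#\\s*", "", h), "[:=\t]\\s*")[[1]]
    if (length(kv) >= 2L) meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  for (key in c("k_spring", "sensitivity", "R_tip", "nu")) {
    if (is.null(meta[[key]]) || is.na(meta[[key]]))
      stop("missing required metadata key: ", key)
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("z", "deflection_V"))
  if (nrow(dat) < 2L) stop("force curve has fewer than 2 samples")
  dz <- diff(dat$z)
  if (!(all(dz > 0) || all(dz < 0))) stop("piezo position must be strictly monotone")
  methods::new("ForceCurve", z = dat$z,
               d = dat$deflection_V * meta$sensitivity,
               kSpring = meta$k_spring, sensitivity = meta$sensitivity,
               RTip = meta$R_tip, nu = meta$nu,
               direction = if (all(dz > 0)) "approach" else "retract")
}

#' Write a force curve in the TSV exchange format
#'
#' @param curve a [ForceCurve-class].
#' @param path output file.
#' @export
writeForceCurve <- function(curve, path) {
  header <- c(sprintf("# k_spring: %.17g", curve@kSpring),
              sprintf("# sensitivity: %.17g", curve@sensitivity),
              sprintf("# R_tip: %.17g", curve@RTip),
              sprintf("# nu: %.17g", curve@nu))
  body <- sprintf("%.17g\t%.17g", curve@z, curve@d / curve@sensitivity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Force and indentation from a curve and contact point
#'
#' `F = k d`; indentation `delta = (z - z0) - d` (piezo displacement minus
#' cantilever deflection, the standard bead-on-cantilever correction).
#' Points with `delta < 0` are flagged pre-contact and excluded from
#' fitting.
#'
#' @param curve a [ForceCurve-class].
#' @param z0 contact point (m), within the sampled z range.
#' @return list(F, delta, preContact) over all samples.
#' @export
forceIndentation <- function(curve, z0) {
  if (z0 < min(curve@z) || z0 > max(curve@z))
    stop("z0 outside the sampled z range")
  F <- curve@kSpring * curve@d
  delta <- (curve@z - z0) - curve@d
  list(F = F, delta = delta, preContact = delta < 0)
}

#' Estimate the contact point of a force curve
#'
#' z0 is chosen to minimize the residual sum of squares of the linearized
#' spherical-Hertz fit (force on indentation^{3/2}, slope through the
#' origin) over candidates in the sampled range: a coarse pass over the
#' sample positions followed by golden-section refinement. For each
#' candidate the baseline offset is taken as the median force of that
#' candidate's pre-contact segment before fitting (estimating the
#' baseline from a fixed low-force quantile instead biases the contact
#' point early under noise). If no candidate improves on the
#' baseline-only (flat) model, the result carries a "no_contact" flag.
#'
#' @param curve a [ForceCurve-class].
#' @return list(z0, noContact, rss).
#' @export
estimateContactPoint <- function(curve) {
  if (length(curve@z) < 20L) stop("need at least 20 samples")
  F0 <- curve@kSpring * curve@d
  z <- curve@z
  rssAt <- function(z0) {
    b0 <- stats::median(F0[z < z0])
    if (!is.finite(b0)) b0 <- 0
    F <- F0 - b0
    d <- F / curve@kSpring
    delta <- (z - z0) - d
    x <- pmax(delta, 0)^1.5
    post <- x > 0
    if (sum(post) < 3L) return(sum(F^2))
    num <- sum(F[post] * x[post])
    den <- sum(x[post]^2)
    m <- if (den > 0) max(0, num / den) else 0
    sum((F[post] - m * x[post])^2) + sum(F[!post]^2)
  }
  cand <- z[seq(5L, length(z) - 1L)]
  rssGrid <- vapply(cand, rssAt, numeric(1))
  best <- which.min(rssGrid)
  lo <- cand[max(1L, best - 1L)]
  hi <- cand[min(length(cand), best + 1L)]
  opt <- stats::optimize(rssAt, lower = lo, upper = hi, tol = 1e-12)
  z0 <- opt$minimum
  rss0 <- sum((F0 - stats::median(F0))^2)  # flat baseline-only model
  noContact <- !(opt$objective < 0.9 * rss0)
  list(z0 = z0, noContact = noContact, rss = opt$objective)
}

#' Spherical-Hertz fit in a force window
#'
#' Restricts to post-contact points whose force lies between the window
#' fractions of the maximum force (inclusive; default 20%-80%), fits the
#' least-squares slope m of F on delta^{3/2} through the origin, and
#' converts it to the Young's modulus `E = 3 m (1 - nu^2) / (4 sqrt(R))`.
#'
#' @param F force samples (N).
#' @param delta indentation samples (m); pre-contact points may be
#'   negative and are ignored.
#' @param RTip sphere radius (m).
#' @param nu Poisson ratio (default 0.5).
#' @param window force-fraction bounds (default c(0.2, 0.8)).
#' @param z0 contact point recorded in the result (default NA).
#' @return a [HertzFit-class]; rejected fits carry qcFlags.
#' @export
hertzFit <- function(F, delta, RTip, nu = 0.5, window = c(0.2, 0.8),
                     z0 = NA_real_) {
  stopifnot(length(F) == length(delta), RTip > 0)
  Fmax <- max(F)
  inWin <- delta > 0 & F >= window[1] * Fmax & F <= window[2] * Fmax
  nPts <- sum(inWin)
  if (nPts < 5L) {
    return(methods::new("HertzFit", E = NA_real_, z0 = z0, window = window,
                        rSquared = NA_real_, nPoints = as.integer(nPts),
                        qcFlags = "too_few_points"))
  }
  x <- delta[inWin]^1.5
  y <- F[inWin]
  m <- sum(y * x) / sum(x^2)
  if (m <= 0) {
    return(methods::new("HertzFit", E = NA_real_, z0 = z0, window = window,
                        rSquared = NA_real_, nPoints = as.integer(nPts),
                        qcFlags = "negative_slope"))
  }
  rss <- sum((y - m * x)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  E <- 3 * m * (1 - nu^2) / (4 * sqrt(RTip))
  methods::new("HertzFit", E = E, z0 = z0, window = window,
               rSquared = r2, nPoints = as.integer(nPts),
               qcFlags = character())
}

#' Full per-curve analysis: contact point + Hertz fit
#'
#' Convenience wrapper chaining [estimateContactPoint()],
#' [forceIndentation()] and [hertzFit()].
#'
#' @param curve a [ForceCurve-class].
#' @param window force-fraction bounds (default c(0.2, 0.8)).
#' @return a [HertzFit-class].
#' @export
fitForceCurve <- function(curve, window = c(0.2, 0.8)) {
  cp <- estimateContactPoint(curve)
  if (cp$noContact) {
    return(methods::new("HertzFit", E = NA_real_, z0 = cp$z0,
                        window = window, rSquared = NA_real_,
                        nPoints = 0L, qcFlags = "no_contact"))
  }
  fi <- forceIndentation(curve, cp$z0)
  hertzFit(fi$F, fi$delta, curve@RTip, nu = curve@nu, window = window,
           z0 = cp$z0)
}

#' QC filter over a list of Hertz fits
#'
#' Rejects fits with r-squared below `r2Min`, any pre-existing QC flag
#' (e.g. "no_contact"), or modulus above `EMax` (substrate artefacts:
#' unphysically stiff values).
#'
#' @param fits list of [HertzFit-class].
#' @param r2Min minimum r-squared (default 0.9).
#' @param EMax modulus cap in Pa (default 1e6 = 1 MPa).
#' @return list(accepted = list of fits, rejected = data.frame(index,
#'   reason)).
#' @export
qcFilter <- function(fits, r2Min = 0.9, EMax = 1e6) {
  reasons <- character()
  idx <- integer()
  keep <- logical(length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (length(f@qcFlags)) {
      idx <- c(idx, i); reasons <- c(reasons, f@qcFlags[1])
    } else if (!is.finite(f@rSquared) || f@rSquared < r2Min) {
      idx <- c(idx, i); reasons <- c(reasons, "low_r_squared")
    } else if (f@E > EMax) {
      idx <- c(idx, i); reasons <- c(reasons, "unphysically_stiff")
    } else {
      keep[i] <- TRUE
    }
  }
  list(accepted = fits[keep],
       acceptedIndex = which(keep),
       rejected = data.frame(index = idx, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Assemble a gridded Young's-modulus map
#'
#' @param fits list of [HertzFit-class] (accepted fits carry E; others NA).
#' @param coords two-column (row, col) matrix of 1-based grid positions,
#'   one per fit; duplicates are an error.
#' @param shape grid shape (default c(24, 24)).
#' @param mask optional logical matrix of excluded positions (e.g. hair
#'   shaft); masked entries carry no E.
#' @param pixelPitch grid pitch in m (default 40e-6 / 24).
#' @return a [StiffnessMap-class]; summary stats (median, mean, n over
#'   accepted unmasked entries) in `attr(, "summary")`.
#' @export
buildStiffnessMap <- function(fits, coords, shape = c(24L, 24L), mask = NULL,
                              pixelPitch = 40e-6 / 24) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(fits), ncol(coords) == 2L)
  if (any(coords[, 1] < 1 | coords[, 1] > shape[1] |
          coords[, 2] < 1 | coords[, 2] > shape[2]))
    stop("grid coordinates outside the declared shape")
  if (anyDuplicated(coords)) stop("duplicate grid coordinate")
  if (is.null(mask)) mask <- matrix(FALSE, shape[1], shape[2])
  stopifnot(identical(dim(mask), as.integer(shape)))
  E <- matrix(NA_real_, shape[1], shape[2])
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (length(f@qcFlags) == 0L && is.finite(f@E))
      E[coords[i, 1], coords[i, 2]] <- f@E
  }
  E[mask] <- NA_real_
  map <- methods::new("StiffnessMap", E = E, mask = mask,
                      pixelPitch = pixelPitch)
  ok <- !is.na(E) & !mask
  attr(map, "summary") <- list(median = stats::median(E[ok]),
                               mean = mean(E[ok]), n = sum(ok))
  map
}

#' Compare Young's-modulus samples between two regions
#'
#' Two-tailed Mann-Whitney U (exact enumeration when both samples have at
#' most 8 observations, tie-corrected normal approximation otherwise) with
#' per-region medians.
#'
#' @param a,b numeric modulus samples (Pa), each >= 3 values.
#' @return list(medianA, medianB, U, p).
#' @export
compareRegions <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("both samples need >= 3 values")
  res <- rankSumTest(a, b, exactMax = 8L)
  list(medianA = stats::median(a), medianB = stats::median(b),
       U = res$statistic, p = res$p.value)
}

#' Export a stiffness map
#'
#' Writes the modulus grid as a CSV matrix and the summary as JSON.
#'
#' @param map a [StiffnessMap-class].
#' @param prefix path prefix; `<prefix>.csv` and `<prefix>.json` written.
#' @export
writeStiffnessMap <- function(map, prefix) {
  utils::write.table(map@E, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(attr(map, "summary"), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
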