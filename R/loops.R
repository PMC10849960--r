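## Connecting the five scaffold helices into one chain with short geometric
## loops: Hermite-arc CA interpolation at each junction followed by
## ideal-template backbone completion. Deterministic and desk-scale; no
## fragment libraries or kinematic closure.

#' ConnectionPlan: helix wiring order and loop budget
#'
#' @slot order permutation of the five helix indices (visit order).
#' @slot reversed logical(5); TRUE where a helix is traversed C-to-N.
#' @slot loopLengths integer(4) loop residue counts per junction.
#' @slot gaps numeric(4) end-to-start Euclidean gaps (Angstrom).
#' @export
setClass("ConnectionPlan",
  representation(order = "integer", reversed = "logical",
                 loopLengths = "integer", gaps = "numeric"))

setValidity("ConnectionPlan", function(object) {
  k <- length(object@order)
  msg <- character()
  if (!identical(sort(object@order), seq_len(k)))
    msg <- c(msg, "order must be a permutation of the helix indices")
  if (length(object@reversed) != k) msg <- c(msg, "reversed must match the helix count")
  if (length(object@loopLengths) != k - 1L || any(object@loopLengths < 1L))
    msg <- c(msg, "need one positive loop length per junction")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConnectionPlan", function(object) {
  cat(sprintf("ConnectionPlan: order %s, loops %s, total gap %.1f A\n",
              paste(ifelse(object@reversed[object@order],
                           paste0(object@order, "'"), object@order), collapse = "-"),
              paste(object@loopLengths, collapse = "/"), sum(object@gaps)))
})

allPermutations <- function(k) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  perms(seq_len(k))
}

#' Enumerate admissible helix connection plans
#'
#' Scores every visit order x traversal direction combination (5! x 2^5) by
#' total end-to-start gap and retains those whose every junction gap can be
#' bridged by a loop of at most \code{loopLenRange[2]} residues (gap <=
#' maxLoop x 3.8 A + 2 A). Plans are ranked by total gap, ascending.
#'
#' @param candidate a \linkS4class{ScaffoldCandidate} or list of two to five
#'   \linkS4class{BackboneChain}.
#' @param loopLenRange inclusive range of loop lengths (residues).
#' @param maxPlans maximum number of ranked plans returned.
#' @return list of \linkS4class{ConnectionPlan}, possibly empty.
#' @export
enumeratePlans <- function(candidate, loopLenRange = c(2L, 5L), maxPlans = 50L) {
  chains <- if (is(candidate, "ScaffoldCandidate")) candidate@chains else candidate
  k <- length(chains)
  stopifnot(k >= 2L, k <= 5L)
  ends <- lapply(chains, function(ch) {
    ca <- caCoords(ch)
    list(first = ca[1, ], last = ca[nrow(ca), ])
  })
  maxGap <- loopLenRange[2] * 3.8 + 2
  dirGrid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  plans <- list()
  totals <- numeric(0)
  for (ord in allPermutations(k)) {
    for (r in seq_len(nrow(dirGrid))) {
      rev5 <- dirGrid[r, ]
      gaps <- numeric(k - 1)
      ok <- TRUE
      for (j in seq_len(k - 1)) {
        hA <- ord[j]; hB <- ord[j + 1]
        exitP <- if (rev5[hA]) ends[[hA]]$first else ends[[hA]]$last
        entryP <- if (rev5[hB]) ends[[hB]]$last else ends[[hB]]$first
        gaps[j] <- sqrt(sum((exitP - entryP)^2))
        if (gaps[j] > maxGap) { ok <- FALSE; break }
      }
      if (!ok) next
      loops <- pmax(loopLenRange[1], ceiling((gaps - 2) / 3.8))
      plans[[length(plans) + 1L]] <-
        new("ConnectionPlan", order = as.integer(ord), reversed = as.logical(rev5),
            loopLengths = as.integer(loops), gaps = gaps)
      totals <- c(totals, sum(gaps))
    }
  }
  plans[order(totals)][seq_len(min(length(plans), maxPlans))]
}

## cubic Hermite curve between P0 and P1 with tangents m0, m1
hermitePoints <- function(P0, P1, m0, m1, s) {
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  outer(h00, P0) + outer(h10, m0) + outer(h01, P1) + outer(h11, m1)
}

## interpolate one loop: L interior CA points with equal-arclength steps in
## [3.6, 4.0] A, or NULL if no loop length in range can satisfy the spacing
buildLoopCA <- function(exitP, exitDir, entryP, entryDir, loopLenRange) {
  sgrid <- seq(0, 1, length.out = 401)
  ## walk L points along the curve at a fixed chord length c, then check
  ## that the final chord to the entry point also lands in the CA window
  walkChords <- function(pts, L, c) {
    out <- matrix(NA_real_, L, 3)
    p <- pts[1, ]; k <- 1L
    for (r in seq_len(L)) {
      found <- FALSE
      while (k < nrow(pts)) {
        k <- k + 1L
        dk <- sqrt(sum((pts[k, ] - p)^2))
        if (dk >= c) {
          dprev <- sqrt(sum((pts[k - 1, ] - p)^2))
          w <- (c - dprev) / max(dk - dprev, 1e-12)
          out[r, ] <- pts[k - 1, ] + w * (pts[k, ] - pts[k - 1, ])
          p <- out[r, ]
          k <- k - 1L
          found <- TRUE
          break
        }
      }
      if (!found) return(NULL)
    }
    out
  }
  taus <- c(3, 5, 8, 12, 18, 26, 38)
  cgrid <- seq(3.62, 3.98, by = 0.04)
  for (L in seq(loopLenRange[1], loopLenRange[2])) {
    for (tau in taus) {
      pts <- hermitePoints(exitP, entryP, exitDir * tau, entryDir * tau, sgrid)
      arc <- sum(sqrt(rowSums(diff(pts)^2)))
      if (arc < 3.6 * (L + 1) || arc > 4.8 * (L + 1)) next
      for (c in cgrid) {
        loopCA <- walkChords(pts, L, c)
        if (is.null(loopCA)) next
        last <- sqrt(sum((entryP - loopCA[L, ])^2))
        if (last >= 3.6 && last <= 4.0) return(loopCA)
      }
    }
  }
  ## fallback: circular arc with exactly equal chords. A circle through both
  ## junction points subtending L+1 chords of length c always exists when
  ## (L+1) c > gap; tangent continuity is given up, the CA-step window is
  ## met exactly.
  gap <- sqrt(sum((entryP - exitP)^2))
  u <- (entryP - exitP) / max(gap, 1e-9)
  perp <- function(v) {
    w <- v - sum(v * u) * u
    n <- sqrt(sum(w^2))
    if (n < 1e-6) NULL else w / n
  }
  bCand <- Filter(Negate(is.null),
                  list(perp(exitDir - entryDir), perp(exitDir + entryDir),
                       perp(crossProduct(u, exitDir)),
                       perp(if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))))
  if (!length(bCand)) return(NULL)
  for (L in seq(loopLenRange[1], loopLenRange[2])) {
    c <- max(3.65, min(3.95, gap / (L + 1) + 0.2))
    if ((L + 1) * c <= gap + 1e-6) next
    ## solve for the circle radius by bisection
    lo <- c / (2 * sin(pi / (L + 1))) + 1e-6
    hi <- 2000
    f <- function(R) 2 * R * sin((L + 1) * asin(pmin(1, c / (2 * R)))) - gap
    if (f(hi) < 0) next
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    R <- (lo + hi) / 2
    theta <- (L + 1) * 2 * asin(min(1, c / (2 * R)))
    for (b in bCand) {
      h <- sqrt(max(R^2 - (gap / 2)^2, 0))
      ctr <- (exitP + entryP) / 2 - h * b
      ## rotate exitP about the axis through ctr normal to the (u, b) plane
      ax <- crossProduct(u, b)
      sgn <- if (sum(crossProduct(exitP - ctr, entryP - ctr) * ax) >= 0) 1 else -1
      loopCA <- t(vapply(seq_len(L), function(k) {
        Rk <- rotationMatrix(ax, sgn * (theta * k / (L + 1)) * 180 / pi)
        ctr + drop(Rk %*% (exitP - ctr))
      }, numeric(3)))
      steps <- sqrt(rowSums(diff(rbind(exitP, loopCA, entryP))^2))
      if (all(steps >= 3.6 & steps <= 4.0)) return(loopCA)
    }
  }
  NULL
}

#' Close a scaffold candidate into a single chain
#'
#' Assembles the five helices in the plan's order and directions and builds
#' each junction loop as a smooth interpolating arc with CA steps in
#' [3.6, 4.0] A; the full backbone is then completed from the CA trace.
#' Helix CA coordinates are preserved exactly; the result is renumbered
#' 1..N with a mapping table back to the source helices.
#'
#' @param candidate a \linkS4class{ScaffoldCandidate} or list of two to five
#'   \linkS4class{BackboneChain}.
#' @param plan a \linkS4class{ConnectionPlan} (for example from
#'   \code{\link{enumeratePlans}}).
#' @param loopLenRange inclusive range of loop lengths (residues).
#' @return on success, a list with \code{chain} (\linkS4class{BackboneChain}),
#'   and \code{mapping} (data.frame: position, source, source_res); on
#'   geometric failure, a list of class \code{"loopFailure"} with the
#'   0-based \code{junction} index.
#' @export
closeLoops <- function(candidate, plan, loopLenRange = c(2L, 5L)) {
  chains <- if (is(candidate, "ScaffoldCandidate")) candidate@chains else candidate
  validObject(plan)
  seqs <- list(); src <- character(0); srcRes <- integer(0)
  caParts <- list()
  for (j in seq_along(chains)) {
    h <- plan@order[j]
    ca <- caCoords(chains[[h]])
    if (plan@reversed[h]) ca <- ca[rev(seq_len(nrow(ca))), , drop = FALSE]
    if (j > 1) {
      prev <- caParts[[length(caParts)]]
      exitP <- prev[nrow(prev), ]
      exitDir <- unitVector(exitP - prev[nrow(prev) - 1, ])
      entryP <- ca[1, ]
      entryDir <- unitVector(ca[2, ] - ca[1, ])
      loopCA <- buildLoopCA(exitP, exitDir, entryP, entryDir, loopLenRange)
      if (is.null(loopCA))
        return(structure(list(junction = j - 2L,
                              reason = "no loop length satisfies CA spacing"),
                         class = "loopFailure"))
      caParts[[length(caParts) + 1L]] <- loopCA
      src <- c(src, rep(paste0("loop", j - 1), nrow(loopCA)))
      srcRes <- c(srcRes, seq_len(nrow(loopCA)))
    }
    caParts[[length(caParts) + 1L]] <- ca
    src <- c(src, rep(paste0("helix", h), nrow(ca)))
    srcRes <- c(srcRes, seq_len(nrow(ca)))
  }
  ca <- do.call(rbind, caParts)
  n <- nrow(ca)
  ## non-local self-clash screen on the closed chain
  d2 <- crossDist2(ca, ca)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  bad <- which(d2 < 3.5^2 & sep > 2, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]
    loopsBefore <- sum(grepl("^loop", unique(src[seq_len(i)])))
    return(structure(list(junction = max(0L, loopsBefore - 1L),
                          reason = "non-local CA clash in closed chain"),
                     class = "loopFailure"))
  }
  bb <- completeBackbone(ca)
  list(chain = BackboneChain(bb$N, ca, bb$C, bb$O, chain = "A"),
       mapping = data.frame(position = seq_len(n), source = src,
                            source_res = srcRes))
}
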