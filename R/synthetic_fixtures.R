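# Idealized 7TM receptor families with known ground truth.
#
# The generator stands in for a crystal-structure benchmark: helices are
# ideal (1.5 A rise, 100 deg/residue twist) on a circular bundle, loops are
# smooth arcs, and families are evolved from one ancestor by point
# mutations, loop indels and coordinate noise, with every edit logged so
# the true alignment is known by construction.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Resample n_out points at equal arc length along a polyline (rows = points).
resample_polyline <- function(pts, n_out) {
  seglen <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  targets <- seq(0, total, length.out = n_out)
  out <- matrix(NA_real_, n_out, 3L)
  for (i in seq_len(n_out)) {
    t <- targets[i]
    j <- max(which(cum <= t + 1e-12))
    if (j >= nrow(pts)) { out[i, ] <- pts[nrow(pts), ]; next }
    f <- (t - cum[j]) / max(seglen[j], 1e-12)
    out[i, ] <- pts[j, ] + f * (pts[j + 1L, ] - pts[j, ])
  }
  out
}

bezier_cubic <- function(p0, c1, c2, p1, n = 400L) {
  t <- seq(0, 1, length.out = n)
  outer((1 - t)^3, p0) + outer(3 * (1 - t)^2 * t, c1) +
    outer(3 * (1 - t) * t^2, c2) + outer(t^3, p1)
}

# Dense loop path: a cubic Bezier with laterally separated control points
# at height h (rounded apex), optionally routed through a via point with a
# continuous tangent there (two cubics sharing the tangent).
dense_loop_curve <- function(p0, p1, h, apex_base, apex_dir,
                             via = NULL, via_tangent = NULL) {
  lat <- 0.2 * (p1 - p0)
  if (is.null(via)) {
    bezier_cubic(p0, apex_base + h * apex_dir - lat,
                 apex_base + h * apex_dir + lat, p1, 800L)
  } else {
    t <- via_tangent
    a <- bezier_cubic(p0, (p0 + via) / 2 + h * apex_dir, via - 4.0 * t, via, 400L)
    b <- bezier_cubic(via, via + 4.0 * t, (via + p1) / 2 + h * apex_dir, p1, 400L)
    rbind(a, b[-1L, , drop = FALSE])
  }
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Forward/backward chain evening (FABRIK): pulls a chain with fixed
# endpoints toward uniform link length while keeping its overall shape.
even_chain <- function(pts, spacing = 3.8, iters = 60L) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  p0 <- pts[1L, ]; p1 <- pts[n, ]
  safe_unit <- function(v) if (vnorm(v) < 1e-9) c(1, 0, 0) else v / vnorm(v)
  for (it in seq_len(iters)) {
    pts[n, ] <- p1
    for (i in (n - 1L):1L) pts[i, ] <- pts[i + 1L, ] + spacing * safe_unit(pts[i, ] - pts[i + 1L, ])
    pts[1L, ] <- p0
    for (i in 2:n) pts[i, ] <- pts[i - 1L, ] + spacing * safe_unit(pts[i, ] - pts[i - 1L, ])
  }
  pts[n, ] <- p1
  pts
}

# Interior CA positions of a loop of n residues between fixed endpoints:
# the apex height of the Bezier path is solved so the path's arc length is
# (n+1) * 3.8 A, then points are spaced evenly along it.
loop_arc <- function(p0, p1, n, apex_base, apex_dir, via = NULL,
                     via_tangent = NULL, spacing = 3.8) {
  need <- (n + 1L) * spacing
  direct <- vnorm(p1 - p0)
  if (direct > need)
    stop("geometric impossibility: loop of ", n,
         " residues cannot span ", round(direct, 1), " A")
  f <- function(h) polyline_length(dense_loop_curve(p0, p1, h, apex_base,
                                                    apex_dir, via, via_tangent)) - need
  if (f(0) >= 0) h <- 0
  else {
    hi <- 5
    while (f(hi) < 0 && hi < 500) hi <- hi * 2
    h <- stats::uniroot(f, c(0, hi), tol = 1e-6)$root
  }
  dense <- dense_loop_curve(p0, p1, h, apex_base, apex_dir, via, via_tangent)
  res <- even_chain(resample_polyline(dense, n + 2L), spacing)
  res[-c(1L, n + 2L), , drop = FALSE]
}

# Soft de-clash of the assembled CA trace: residues in `mobile_ranges`
# (loops and termini; each range a chain whose flanking residues are fixed)
# are pushed apart wherever two residues more than one position apart come
# closer than `min_d`, then each chain is re-evened. `skip_pairs` (e.g. the
# planted disulfide) are exempt.
declash_trace <- function(ca, mobile_ranges, min_d = 4.2, skip_pairs = NULL,
                          iters = 40L) {
  n <- nrow(ca)
  mobile <- logical(n)
  for (r in mobile_ranges) mobile[r] <- TRUE
  for (it in seq_len(iters)) {
    dm <- as.matrix(stats::dist(ca))
    dm[abs(row(dm) - col(dm)) <= 1L] <- Inf
    diag(dm) <- Inf
    if (!is.null(skip_pairs)) for (k in seq_len(nrow(skip_pairs))) {
      dm[skip_pairs[k, 1L], skip_pairs[k, 2L]] <- Inf
      dm[skip_pairs[k, 2L], skip_pairs[k, 1L]] <- Inf
    }
    idx <- which(dm < min_d, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    if (!nrow(idx)) break
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      push <- 0.6 * (min_d - dm[i, j]) * unitv(ca[i, ] - ca[j, ])
      if (mobile[i]) ca[i, ] <- ca[i, ] + push
      if (mobile[j]) ca[j, ] <- ca[j, ] - push
    }
    for (r in mobile_ranges) {
      chain <- c(min(r) - 1L, r, max(r) + 1L)
      chain <- chain[chain >= 1L & chain <= n]
      nf <- length(chain)
      first_fixed <- !mobile[chain[1L]]
      last_fixed <- !mobile[chain[nf]]
      if (first_fixed && last_fixed) {
        ca[chain, ] <- even_chain(ca[chain, , drop = FALSE], 3.8, iters = 30L)
      } else if (first_fixed) {
        for (q in 2:nf)
          ca[chain[q], ] <- ca[chain[q - 1L], ] +
            3.8 * unitv(ca[chain[q], ] - ca[chain[q - 1L], ])
      } else {
        for (q in (nf - 1L):1L)
          ca[chain[q], ] <- ca[chain[q + 1L], ] +
            3.8 * unitv(ca[chain[q], ] - ca[chain[q + 1L], ])
      }
    }
  }
  ca
}

# Full backbone [L,5,3] from a CA trace: N and C along the chords to the
# neighbouring CAs, O perpendicular. CB is built from a stable local frame
# (tangent + curvature normal, with a deterministic fallback perpendicular
# for straight stretches) so its direction never degenerates -- the
# chord-based ideal-CB rule collapses when the trace is locally collinear.
backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  co <- empty_coords(n)
  co[, "CA", ] <- ca
  for (i in seq_len(n)) {
    prev <- if (i > 1L) ca[i - 1L, ] else ca[i, ] - (ca[i + 1L, ] - ca[i, ])
    nxt <- if (i < n) ca[i + 1L, ] else ca[i, ] - (ca[i - 1L, ] - ca[i, ])
    Ni <- ca[i, ] + 1.45 * unitv(prev - ca[i, ])
    Ci <- ca[i, ] + 1.52 * unitv(nxt - ca[i, ])
    e1 <- unitv(nxt - ca[i, ])
    pv <- (prev - ca[i, ]) - sum((prev - ca[i, ]) * e1) * e1
    e2 <- if (vnorm(pv) > 1e-6) unitv(pv) else unitv(cross3(e1, c(0, 0, 1) + 1e-3))
    co[i, "N", ] <- Ni
    co[i, "C", ] <- Ci
    co[i, "O", ] <- Ci + 1.23 * unitv(cross3(e1, e2))
    tg <- unitv(nxt - prev)
    cv <- (prev + nxt) / 2 - ca[i, ]
    cperp <- cv - sum(cv * tg) * tg
    if (vnorm(cperp) < 0.3) {
      # straight stretch: deterministic perpendicular of the tangent
      ax <- diag(3L)[, which.min(abs(tg))]
      cperp <- cross3(tg, ax)
    }
    nn <- unitv(cperp)
    co[i, "CB", ] <- ca[i, ] + 1.53 * unitv(-nn + 0.8 * cross3(tg, nn))
  }
  co
}

#' Generate an idealized seven-transmembrane receptor
#'
#' Builds a ReceptorEntry with ideal alpha-helical TM segments (1.5 A rise
#' per residue, 100 degrees twist) whose axes sit on a circle with
#' alternating up/down direction, smooth-arc loops, short curved termini,
#' Ballesteros-Weinstein anchors at helix midpoints, planted class-A anchor
#' motifs (GN, D, DRY, W, P, CWxP, NPxxY, and xWxxG in ECL1), and one
#' TM3--ECL2 disulfide pair. The ECL2 arc is routed past the extracellular
#' end of TM3 so that the planted disulfide is geometrically satisfied.
#'
#' @param n_helices number of helices (7 for a GPCR).
#' @param helix_length residues per helix.
#' @param loop_lengths integer vector of the six loop lengths in order
#'   ICL1, ECL1, ICL2, ECL2, ICL3, ECL3.
#' @param nterm,cterm residues in the termini.
#' @param bundle_radius radius (A) of the circle holding the helix axes.
#' @param seed RNG seed (sequence sampling).
#' @return a [receptor_entry] with coordinates, TM segments, anchors and a
#'   disulfide annotation; attributes `protected` (positions exempt from
#'   mutation: anchors, motifs, disulfide cysteines) and `regions`
#'   (residue-position masks for TM1..TM7, loops and termini).
#' @export
make_ideal_bundle <- function(n_helices = 7L, helix_length = 18L,
                              loop_lengths = c(5L, 5L, 5L, 12L, 7L, 5L),
                              nterm = 3L, cterm = 3L,
                              bundle_radius = 11, seed = 1L) {
  stopifnot(n_helices == 7L, helix_length >= 9L, all(loop_lengths >= 3L),
            nterm >= 1L, cterm >= 1L)
  set.seed(seed)
  rise <- 1.5; twist <- 100 * pi / 180; hrad <- 2.3
  H <- (helix_length - 1L) * rise
  phi <- 2 * pi * (0:6) / 7
  axis_xy <- cbind(bundle_radius * cos(phi), bundle_radius * sin(phi))
  updown <- ifelse(seq_len(7L) %% 2L == 1L, -1, 1)  # odd helices run ec -> ic

  helix_ca <- vector("list", 7L)
  for (h in seq_len(7L)) {
    k <- 0:(helix_length - 1L)
    z0 <- if (updown[h] < 0) H / 2 else -H / 2
    z <- z0 + updown[h] * k * rise
    th <- phi[h] + updown[h] * k * twist
    helix_ca[[h]] <- cbind(axis_xy[h, 1L] + hrad * cos(th),
                           axis_xy[h, 2L] + hrad * sin(th),
                           z)
  }

  # curved terminus extending from an end CA, away from the membrane
  terminus <- function(from, prev, n, zsign) {
    dir <- unitv(unitv(from - prev) + c(0, 0, 0.6 * zsign))
    radial <- unitv(c(from[1L], from[2L], 0))
    pts <- matrix(NA_real_, n, 3L)
    p <- from
    for (i in seq_len(n)) {
      dir <- unitv(dir + 0.25 * radial)   # gentle outward curl
      p <- p + 3.8 * dir
      pts[i, ] <- p
    }
    pts
  }

  loop_names <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  # ECL2 is routed through a via point just above the TM3 cysteine (second
  # residue from the extracellular end of TM3) so the conserved disulfide
  # is geometrically plausible
  tm3cys_ca <- helix_ca[[3L]][2L, ]
  ecl2_mid <- (helix_ca[[4L]][helix_length, ] + helix_ca[[5L]][1L, ]) / 2
  # approach the TM3 cysteine from the TM4/TM5 side (where ECL2 lives) so
  # the route stays clear of ECL1
  appr <- unitv(unitv(c(ecl2_mid[1L] - tm3cys_ca[1L],
                        ecl2_mid[2L] - tm3cys_ca[2L], 0)) + c(0, 0, 0.9))
  ecl2_via <- tm3cys_ca + 4.8 * appr

  loops <- vector("list", 6L)
  loop_arcs <- list()
  for (j in seq_len(6L)) {
    p0 <- helix_ca[[j]][helix_length, ]
    p1 <- helix_ca[[j + 1L]][1L, ]
    zsign <- if (p0[3L] > 0) 1 else -1
    mid <- (p0 + p1) / 2
    base <- c(1.3 * mid[1L], 1.3 * mid[2L], mid[3L])
    via <- NULL; vtan <- NULL
    if (loop_names[j] == "ECL2") {
      via <- ecl2_via
      vtan <- unitv(p1 - p0)
    }
    loops[[j]] <- loop_arc(p0, p1, loop_lengths[j], base, c(0, 0, zsign),
                           via = via, via_tangent = vtan)
    loop_arcs[[loop_names[j]]] <- list(p0 = p0, p1 = p1, base = base,
                                       dir = c(0, 0, zsign),
                                       via = via, via_tangent = vtan)
  }

  nt <- terminus(helix_ca[[1L]][1L, ], helix_ca[[1L]][2L, ], nterm, 1)
  ct <- terminus(helix_ca[[7L]][helix_length, ],
                 helix_ca[[7L]][helix_length - 1L, ], cterm, -1)

  ca <- rbind(nt[rev(seq_len(nterm)), , drop = FALSE])
  seg <- data.frame(helix = integer(0), start = integer(0),
                    end = integer(0), anchor = integer(0))
  pos <- nterm
  loop_bounds <- list()
  for (h in seq_len(7L)) {
    start <- pos + 1L
    ca <- rbind(ca, helix_ca[[h]])
    pos <- pos + helix_length
    seg <- rbind(seg, data.frame(helix = h, start = start, end = pos,
                                 anchor = start + (helix_length - 1L) %/% 2L))
    if (h < 7L) {
      lstart <- pos + 1L
      ca <- rbind(ca, loops[[h]])
      pos <- pos + loop_lengths[h]
      loop_bounds[[loop_names[h]]] <- c(lstart, pos)
    }
  }
  ca <- rbind(ca, ct)
  L <- nrow(ca)
  mobile <- c(unname(loop_bounds), list(c(1L, nterm), c(L - cterm + 1L, L)))
  mobile <- lapply(mobile, function(b) b[1L]:b[2L])
  ca <- declash_trace(ca, mobile)
  co <- backbone_from_ca(ca)

  sq <- sample(AA20, L, replace = TRUE)
  protected <- integer(0)
  put <- function(at, letters) {
    sq[at] <<- letters
    protected <<- c(protected, at)
  }
  a <- seg$anchor
  put(c(a[1L] - 1L, a[1L]), c("G", "N"))                      # 1.49-1.50
  put(a[2L], "D")                                             # 2.50
  put((a[3L] - 1L):(a[3L] + 1L), c("D", "R", "Y"))            # DRY, R = 3.50
  put(a[4L], "W")                                             # 4.50
  put(a[5L], "P")                                             # 5.50
  put(c(a[6L] - 3L, a[6L] - 2L, a[6L]), c("C", "W", "P"))     # CWxP, P = 6.50
  put(c(a[7L] - 1L, a[7L], a[7L] + 3L), c("N", "P", "Y"))     # NPxxY, P = 7.50
  e1 <- loop_bounds[["ECL1"]]
  put(c(e1[1L] + 1L, e1[1L] + 4L), c("W", "G"))               # xWxxG
  # conserved TM3-ECL2 disulfide
  tm3_cys <- seg$start[3L] + 1L
  e2 <- loop_bounds[["ECL2"]]
  e2_idx <- e2[1L]:e2[2L]
  d <- sqrt(rowSums(sweep(ca[e2_idx, , drop = FALSE], 2, ca[tm3_cys, ])^2))
  ecl2_cys <- e2_idx[which.min(d)]
  put(c(tm3_cys, ecl2_cys), c("C", "C"))
  # disulfide-bonded side chains face each other: re-orient both CB
  # vectors toward the partner CA (blended with the frame direction)
  for (pr in list(c(tm3_cys, ecl2_cys), c(ecl2_cys, tm3_cys))) {
    toward <- unitv(ca[pr[2L], ] - ca[pr[1L], ])
    old <- unitv(co[pr[1L], "CB", ] - ca[pr[1L], ])
    co[pr[1L], "CB", ] <- ca[pr[1L], ] + 1.53 * unitv(0.75 * toward + 0.25 * old)
  }

  regions <- list()
  for (h in seq_len(7L)) regions[[paste0("TM", h)]] <- seg$start[h]:seg$end[h]
  for (nm in names(loop_bounds)) regions[[nm]] <- loop_bounds[[nm]][1L]:loop_bounds[[nm]][2L]
  regions[["Nterm"]] <- seq_len(nterm)
  regions[["Cterm"]] <- (L - cterm + 1L):L

  entry <- receptor_entry(id = sprintf("ideal7tm_s%d", seed),
                          sequence = paste(sq, collapse = ""),
                          coords = co, tm_segments = seg,
                          disulfides = cbind(tm3_cys, ecl2_cys),
                          class_label = "A")
  attr(entry, "protected") <- sort(unique(protected))
  attr(entry, "regions") <- regions
  attr(entry, "loop_arcs") <- loop_arcs
  entry
}

#' Per-residue region masks of an annotated receptor
#'
#' @param entry a [receptor_entry] with `tm_segments`.
#' @return named list of 1-based residue-position vectors (TM1..TM7,
#'   ICL1..3, ECL1..3, Nterm, Cterm).
#' @export
receptor_regions <- function(entry) {
  r <- attr(entry, "regions")
  if (!is.null(r)) return(r)
  seg <- entry$tm_segments
  if (is.null(seg)) stop("entry has no TM segment annotations")
  L <- nchar(entry$sequence)
  loop_names <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  out <- list()
  for (h in seq_len(nrow(seg))) out[[paste0("TM", seg$helix[h])]] <- seg$start[h]:seg$end[h]
  for (j in seq_len(nrow(seg) - 1L)) {
    a <- seg$end[j] + 1L; b <- seg$start[j + 1L] - 1L
    out[[loop_names[j]]] <- if (a <= b) a:b else integer(0)
  }
  out[["Nterm"]] <- if (seg$start[1L] > 1L) 1:(seg$start[1L] - 1L) else integer(0)
  out[["Cterm"]] <- if (seg$end[nrow(seg)] < L) (seg$end[nrow(seg)] + 1L):L else integer(0)
  out
}

# Pull consecutive-CA distances back into [2.9, 4.7] by shrinking the noise
# displacement of offending residues toward the noise-free base coordinates.
repair_connectivity <- function(ca, base) {
  for (iter in 1:30) {
    d <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
    bad <- which(d < 2.9 | d > 4.7)
    if (!length(bad)) break
    idx <- unique(c(bad, bad + 1L))
    ca[idx, ] <- base[idx, ] + 0.5 * (ca[idx, , drop = FALSE] - base[idx, , drop = FALSE])
  }
  ca
}

#' Point-mutation rate that realises a target pairwise identity
#'
#' A mutation always substitutes one of the 19 alternatives, so two
#' sequences independently mutated from a common ancestor at rate m match
#' at an unprotected site with probability q(m) = (1-m)^2 + m^2/19, and a
#' member matches the ancestor itself with probability q(m) = 1-m.
#' Protected sites (fraction p) always match, so identity =
#' p + (1-p) q(m). Inverts that relation.
#'
#' @param identity_pct target mean pairwise identity, percent.
#' @param protected_frac fraction of sites exempt from mutation.
#' @param relative_to "sibling" (identity between two mutated members,
#'   the default) or "ancestor" (identity of a member to the unmutated
#'   ancestor, for which q(m) = (1-m) + m/19).
#' @return mutation rate in [0, 1].
#' @export
mutation_rate_for_identity <- function(identity_pct, protected_frac = 0,
                                       relative_to = c("sibling", "ancestor")) {
  relative_to <- match.arg(relative_to)
  q <- (identity_pct / 100 - protected_frac) / (1 - protected_frac)
  q <- min(max(q, 1 / 19), 1)
  if (relative_to == "sibling") {
    # (1-m)^2 + m^2/19 = q  =>  (20/19) m^2 - 2 m + (1 - q) = 0
    disc <- max(1 - (20 / 19) * (1 - q), 0)
    min(max((1 - sqrt(disc)) * 19 / 20, 0), 1)
  } else {
    min(max(1 - q, 0), 1)
  }
}

#' Evolve a synthetic receptor family from an ancestor
#'
#' Members are derived by point mutations at unprotected sites, rare
#' single-residue indels restricted to loops, per-atom Gaussian coordinate
#' noise, and (optionally) rigid loop displacement. All edits are logged
#' and the ground-truth alignment is built from them. Deletions re-lay the
#' remaining loop residues along the original arc (that loop is then marked
#' structurally unconserved for the member); insertions add an off-axis
#' residue and leave the rest of the loop in place.
#'
#' @param ancestor a [make_ideal_bundle] entry.
#' @param n_members number of derived members.
#' @param mutation_rate per-site substitution probability; if `NULL`,
#'   derived from `target_identity` via [mutation_rate_for_identity].
#' @param target_identity desired mean pairwise identity (percent) among
#'   members; used only when `mutation_rate` is `NULL`.
#' @param indel_rate per-loop probability of one single-residue indel.
#' @param noise_sigma per-coordinate Gaussian noise (A) on backbone atoms;
#'   consecutive CA distances are repaired into [2.9, 4.7] A afterwards.
#'   May be a vector (recycled over members) to plant accuracy gradients.
#' @param noise_from_identity optional function mapping a member's
#'   realised percent identity to the ancestor to its noise sigma;
#'   overrides `noise_sigma` and ties structural accuracy monotonically to
#'   sequence identity (the premise of identity-bin experiments).
#' @param helix_shift_frac fraction of the member's noise sigma applied as
#'   independent rigid displacement (translation plus a small tilt) of
#'   each TM helix, with loops re-evened between the displaced ends.
#'   Helix-packing shifts are how remote homologs actually diverge in the
#'   TM bundle; atomic noise alone is absorbed by chain-connectivity
#'   repair and rigid superposition. Default 0.
#' @param loop_displace_prob per-loop probability of a rigid ~2 A
#'   displacement (marks the loop unconserved).
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return object of class `fixture_family`: ancestor, `members` (named
#'   list of entries), `truth_alignment` (a [new_msa] over ancestor +
#'   members with region masks and anchor columns; attribute `anc_pos`
#'   gives each column's ancestor position, NA for insertion columns),
#'   `truth_coords`, `loop_conserved` (member x loop logical), `edits`,
#'   and `params`.
#' @export
evolve_family <- function(ancestor, n_members = 9L, mutation_rate = NULL,
                          target_identity = 30, indel_rate = 0.15,
                          noise_sigma = 0.3, noise_from_identity = NULL,
                          helix_shift_frac = 0, loop_displace_prob = 0,
                          seed = 1L) {
  stopifnot(indel_rate >= 0, indel_rate <= 1, noise_sigma >= 0)
  protected <- attr(ancestor, "protected")
  regions <- receptor_regions(ancestor)
  L <- nchar(ancestor$sequence)
  if (is.null(mutation_rate)) {
    mutation_rate <- vapply(target_identity, mutation_rate_for_identity,
                            numeric(1), protected_frac = length(protected) / L)
  }
  stopifnot(all(mutation_rate >= 0), all(mutation_rate <= 1),
            all(noise_sigma >= 0))
  # per-member rates/noise: recycled over members, so accuracy or identity
  # gradients can be planted across one family
  mut_m <- rep_len(mutation_rate, n_members)
  noise_m <- rep_len(noise_sigma, n_members)
  set.seed(seed)
  anc_seq <- strsplit(ancestor$sequence, "")[[1L]]
  loop_names <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")

  members <- list()
  edits <- list()
  # per-member maps: anc position -> member position (NA if deleted), and
  # insertions as data.frame(after_anc, member_pos, letter)
  maps <- list()
  inserts <- list()
  loop_conserved <- matrix(TRUE, n_members, 6L,
                           dimnames = list(NULL, loop_names))

  for (m in seq_len(n_members)) {
    ed <- list()
    del_at <- integer(0)
    ins_after <- integer(0)
    for (j in seq_len(6L)) {
      lp <- regions[[loop_names[j]]]
      if (stats::runif(1) < indel_rate) {
        candidates <- setdiff(lp, protected)
        type <- if (length(lp) >= 5L && length(candidates) >= 2L &&
                    stats::runif(1) < 0.5) "del" else "ins"
        if (type == "del") {
          at <- sample(candidates, 1L)
          del_at <- c(del_at, at)
          loop_conserved[m, j] <- FALSE
          ed[[length(ed) + 1L]] <- data.frame(op = "del", loop = loop_names[j], pos = at)
        } else {
          at <- sample(lp[-length(lp)], 1L)  # insert after this position
          ins_after <- c(ins_after, at)
          ed[[length(ed) + 1L]] <- data.frame(op = "ins", loop = loop_names[j], pos = at)
        }
      }
      if (loop_displace_prob > 0 && stats::runif(1) < loop_displace_prob) {
        loop_conserved[m, j] <- FALSE
        ed[[length(ed) + 1L]] <- data.frame(op = "displace", loop = loop_names[j],
                                            pos = lp[1L])
      }
    }

    # --- sequence + position map ---
    map <- integer(L); map[] <- NA_integer_
    seqs <- character(0)
    ins_rec <- data.frame(after_anc = integer(0), member_pos = integer(0),
                          letter = character(0))
    p <- 0L
    for (i in seq_len(L)) {
      if (!(i %in% del_at)) {
        p <- p + 1L
        map[i] <- p
        seqs[p] <- anc_seq[i]
      }
      if (i %in% ins_after) {
        p <- p + 1L
        newaa <- sample(AA20, 1L)
        seqs[p] <- newaa
        ins_rec <- rbind(ins_rec, data.frame(after_anc = i, member_pos = p,
                                             letter = newaa))
      }
    }
    Lm <- p

    # point mutations at unprotected ancestor sites
    mut_sites <- setdiff(which(!is.na(map)), protected)
    hit <- mut_sites[stats::runif(length(mut_sites)) < mut_m[m]]
    for (i in hit) {
      seqs[map[i]] <- sample(setdiff(AA20, anc_seq[i]), 1L)
      ed[[length(ed) + 1L]] <- data.frame(op = "sub", loop = NA_character_, pos = i)
    }

    if (!is.null(noise_from_identity)) {
      kept0 <- which(!is.na(map))
      idp <- 100 * sum(seqs[map[kept0]] == anc_seq[kept0]) / L
      noise_m[m] <- noise_from_identity(idp)
    }

    # --- coordinates ---
    ca <- matrix(NA_real_, Lm, 3L)
    kept <- which(!is.na(map))
    ca[map[kept], ] <- ancestor$coords[kept, "CA", ]
    for (r in seq_len(nrow(ins_rec))) {
      mp <- ins_rec$member_pos[r]
      nb <- ca[c(mp - 1L, mp + 1L), , drop = FALSE]
      chord <- nb[2L, ] - nb[1L, ]
      nrm <- cross3(chord, c(0, 0, 1))
      if (vnorm(nrm) < 1e-6) nrm <- c(1, 0, 0)
      ca[mp, ] <- (nb[1L, ] + nb[2L, ]) / 2 + 2.4 * unitv(nrm)
    }
    # deletions: regenerate that loop at its new length on the same arc family
    arcs <- attr(ancestor, "loop_arcs")
    for (j in seq_len(6L)) {
      lp <- regions[[loop_names[j]]]
      if (!any(del_at %in% lp)) next
      flank0 <- map[lp[1L] - 1L]; flank1 <- map[lp[length(lp)] + 1L]
      inner <- (flank0 + 1L):(flank1 - 1L)
      ar <- arcs[[loop_names[j]]]
      ca[inner, ] <- loop_arc(ar$p0, ar$p1, length(inner), ar$base, ar$dir,
                              via = ar$via, via_tangent = ar$via_tangent)
    }
    # optional rigid loop displacement
    for (ej in ed) if (ej$op[1L] == "displace") {
      lp <- regions[[ej$loop[1L]]]
      mp <- stats::na.omit(map[lp])
      shift <- stats::rnorm(3L); shift <- 2.0 * unitv(shift)
      ca[mp, ] <- sweep(ca[mp, , drop = FALSE], 2, shift, `+`)
    }
    if (helix_shift_frac > 0 && noise_m[m] > 0) {
      hs <- helix_shift_frac * noise_m[m]
      for (h in seq_len(7L)) {
        seg0 <- ancestor$tm_segments[h, ]
        idx <- map[seg0$start]:map[seg0$end]
        centroid <- colMeans(ca[idx, , drop = FALSE])
        axis <- unitv(stats::rnorm(3L))
        angle <- stats::rnorm(1L, sd = 2.5 * hs) * pi / 180
        K <- matrix(c(0, -axis[3L], axis[2L], axis[3L], 0, -axis[1L],
                      -axis[2L], axis[1L], 0), 3L, 3L, byrow = TRUE)
        R <- diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
        shift <- stats::rnorm(3L, sd = hs)
        ca[idx, ] <- sweep(sweep(ca[idx, , drop = FALSE], 2L, centroid) %*% t(R),
                           2L, centroid + shift, `+`)
      }
      # reconnect loops between the displaced helix ends
      for (j in seq_len(6L)) {
        lp <- regions[[loop_names[j]]]
        inner <- stats::na.omit(map[lp])
        chain <- c(min(inner) - 1L, inner, max(inner) + 1L)
        ca[chain, ] <- even_chain(ca[chain, , drop = FALSE], 3.8, iters = 30L)
      }
      # termini follow their helix: renormalise step lengths outward
      first_tm <- map[ancestor$tm_segments$start[1L]]
      if (first_tm > 1L) for (q in (first_tm - 1L):1L)
        ca[q, ] <- ca[q + 1L, ] + 3.8 * unitv(ca[q, ] - ca[q + 1L, ])
      last_tm <- map[ancestor$tm_segments$end[7L]]
      if (last_tm < Lm) for (q in (last_tm + 1L):Lm)
        ca[q, ] <- ca[q - 1L, ] + 3.8 * unitv(ca[q, ] - ca[q - 1L, ])
    }
    base <- ca
    if (noise_m[m] > 0) {
      # half the displacement is chain-correlated (moving-average filtered
      # white noise): structural divergence is collective, and purely
      # per-atom noise above ~0.8 A would be clipped away by the
      # connectivity repair, capping the realisable accuracy gradient
      white <- matrix(stats::rnorm(3L * Lm), Lm, 3L)
      smooth <- apply(matrix(stats::rnorm(3L * Lm), Lm, 3L), 2L, function(v)
        stats::filter(v, rep(1 / 7, 7L), sides = 2L, circular = TRUE))
      smooth <- smooth * sqrt(7)   # restore unit variance after averaging
      ca <- ca + noise_m[m] * (sqrt(0.5) * white + sqrt(0.5) * smooth)
      ca <- repair_connectivity(ca, base)
    }
    co <- backbone_from_ca(ca)
    # residues inherited from the ancestor keep its side-chain orientation:
    # CB = noisy CA + ancestral CA->CB vector (plus attenuated noise); the
    # chord-based reconstruction is kept only for inserted residues
    cbvec <- ancestor$coords[, "CB", ] - ancestor$coords[, "CA", ]
    mp_kept <- map[kept]
    co[mp_kept, "CB", ] <- ca[mp_kept, , drop = FALSE] + cbvec[kept, , drop = FALSE] +
      matrix(stats::rnorm(3L * length(kept), sd = 0.5 * noise_m[m]),
             length(kept), 3L)

    # --- annotations shifted by the edit script ---
    shift_of <- function(i) map[i]
    seg <- ancestor$tm_segments
    seg$start <- vapply(seg$start, shift_of, integer(1))
    seg$end <- vapply(seg$end, shift_of, integer(1))
    seg$anchor <- vapply(seg$anchor, shift_of, integer(1))
    dis <- ancestor$disulfides
    dis <- matrix(vapply(as.integer(dis), shift_of, integer(1)), ncol = 2L)

    id <- sprintf("m%02d", m)
    members[[id]] <- receptor_entry(id = id, sequence = paste(seqs, collapse = ""),
                                    coords = co, tm_segments = seg,
                                    disulfides = dis, class_label = "A")
    maps[[id]] <- map
    inserts[[id]] <- ins_rec
    edits[[id]] <- if (length(ed)) do.call(rbind, ed) else
      data.frame(op = character(0), loop = character(0), pos = integer(0))
  }

  fam <- structure(list(ancestor = ancestor, members = members,
                        truth_coords = ancestor$coords,
                        loop_conserved = loop_conserved, edits = edits,
                        params = list(n_members = n_members,
                                      mutation_rate = mutation_rate,
                                      indel_rate = indel_rate,
                                      noise_sigma = noise_sigma,
                                      loop_displace_prob = loop_displace_prob,
                                      seed = seed)),
                   class = "fixture_family")
  fam$truth_alignment <- build_truth_alignment(ancestor, members, maps,
                                               inserts, regions)
  fam
}

# Assemble the ground-truth MSA (ancestor + members) from the edit maps.
build_truth_alignment <- function(ancestor, members, maps, inserts, regions) {
  L <- nchar(ancestor$sequence)
  ids <- c(ancestor$id, names(members))
  # column plan: for each ancestor position, its column, then one column
  # per insertion recorded after that position (ordered by member)
  cols <- list()
  anc_pos <- integer(0)
  for (i in seq_len(L)) {
    entry <- c(stats::setNames(i, ancestor$id),
               unlist(lapply(names(members), function(id) {
                 mp <- maps[[id]][i]
                 if (is.na(mp)) NULL else stats::setNames(mp, id)
               })))
    cols[[length(cols) + 1L]] <- entry
    anc_pos <- c(anc_pos, i)
    for (id in names(members)) {
      ins <- inserts[[id]]
      hitr <- which(ins$after_anc == i)
      for (r in hitr) {
        cols[[length(cols) + 1L]] <- stats::setNames(ins$member_pos[r], id)
        anc_pos <- c(anc_pos, NA_integer_)
      }
    }
  }
  W <- length(cols)
  seqs <- c(list(strsplit(ancestor$sequence, "")[[1L]]),
            lapply(members, function(m) strsplit(m$sequence, "")[[1L]]))
  names(seqs) <- ids
  rows <- vapply(ids, function(id) {
    chars <- rep("-", W)
    for (k in seq_len(W)) {
      v <- cols[[k]]
      if (id %in% names(v)) chars[k] <- seqs[[id]][v[[id]]]
    }
    paste(chars, collapse = "")
  }, character(1))

  # each column is owned by its ancestor position; insertion columns by the
  # position they were inserted after (always inside a loop), so the masks
  # partition the column space
  owner <- anc_pos
  for (k in which(is.na(owner))) owner[k] <- owner[k - 1L]
  region_masks <- lapply(regions, function(posv) which(owner %in% posv))
  anchors <- ancestor$tm_segments$anchor
  anchor_columns <- stats::setNames(match(anchors, anc_pos),
                                    sprintf("%d.50", seq_len(7L)))
  dis <- ancestor$disulfides
  disulfide_columns <- c(TM3 = match(dis[1L, 1L], anc_pos),
                         ECL2 = match(dis[1L, 2L], anc_pos))
  msa <- new_msa(rows, region_masks = region_masks,
                 anchor_columns = anchor_columns,
                 disulfide_columns = disulfide_columns,
                 aligned_cols = which(!is.na(anc_pos)))
  attr(msa, "anc_pos") <- anc_pos
  msa
}

#' @export
print.fixture_family <- function(x, ...) {
  cat(sprintf("<fixture_family> %d members of %s (%d aa); mutation rate %.2f, indel rate %.2f, noise %.2f A\n",
              length(x$members), x$ancestor$id, nchar(x$ancestor$sequence),
              x$params$mutation_rate, x$params$indel_rate, x$params$noise_sigma))
  invisible(x)
}
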