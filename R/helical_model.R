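# Helical symmetry of a single-protofilament fibril: (rise, twist)
# geometry, stack construction, screw-symmetry estimation from atomic
# models, and inter-layer contact mapping.

#' Helical screw symmetry
#'
#' The screw operation relating consecutive protein layers of a fibril:
#' an axial translation (`rise`, Angstrom per subunit) combined with a
#' rotation about the fibril axis (`twist`, signed degrees per subunit).
#' Negative twist denotes a left-handed helix.
#'
#' @param rise axial rise per subunit (Angstrom, > 0).
#' @param twist signed twist per subunit (degrees, `0 < |twist| <= 360`).
#' @return a `helical_symmetry` list.
#' @examples
#' helical_symmetry(4.8, -0.58)
#' @export
helical_symmetry <- function(rise, twist) {
  if (rise <= 0) stop("helical_symmetry: rise must be > 0")
  if (twist == 0 || abs(twist) > 360) {
    stop("helical_symmetry: need 0 < |twist| <= 360")
  }
  structure(list(rise = rise, twist = twist), class = "helical_symmetry")
}

#' Pitch, cross-over distance and handedness
#'
#' The helical pitch is the axial distance over which the structure
#' rotates by a full turn, `pitch = rise * 360 / |twist|`; the cross-over
#' distance (between apparent width minima of a twisted 2D projection) is
#' half of it. Handedness follows the twist sign (negative =
#' left-handed).
#'
#' @param sym a [helical_symmetry()].
#' @return list with `pitch` (Angstrom), `crossover` (Angstrom),
#'   `handedness` (`"left"` or `"right"`).
#' @examples
#' pitch_and_crossover(helical_symmetry(4.8, -0.58))  # ~2979 A ~ 298 nm
#' @export
pitch_and_crossover <- function(sym) {
  if (!inherits(sym, "helical_symmetry")) sym <- do.call(helical_symmetry, sym)
  pitch <- sym$rise * 360 / abs(sym$twist)
  list(pitch = pitch, crossover = pitch / 2,
       handedness = if (sym$twist < 0) "left" else "right")
}

# chain labels for up to 62 layers
layer_chain_labels <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) stop("build_stack: more layers than chain labels (cap 62)")
  pool[seq_len(n)]
}

#' Build a fibril stack from one layer and a screw symmetry
#'
#' Layer k is obtained by rotating layer 0 by `k * twist` about the z
#' axis and translating it by `k * rise` along z — a rigid screw
#' operation, so all intra-layer distances are preserved exactly. Chains
#' are relabelled per layer (A, B, C, ...) and `layer` indices run 0 ..
#' `n_layers - 1`.
#'
#' @param layer an [atomic_model()] of one layer (axis = z).
#' @param sym a [helical_symmetry()].
#' @param n_layers number of layers (>= 1; capped at 62 by chain labels).
#' @return an [atomic_model()] of the stack.
#' @examples
#' stk <- build_stack(generate_beta_arch_layer(20), helical_symmetry(4.8, -0.58), 5)
#' @export
build_stack <- function(layer, sym, n_layers) {
  if (!inherits(sym, "helical_symmetry")) sym <- do.call(helical_symmetry, sym)
  if (n_layers < 1) stop("build_stack: n_layers must be >= 1")
  labels <- layer_chain_labels(n_layers)
  xyz <- coords(layer)
  out <- lapply(seq_len(n_layers) - 1L, function(k) {
    ang <- k * sym$twist * pi / 180
    R <- rotation_about_axis(c(0, 0, 1), ang)
    p <- xyz %*% t(R)
    df <- as.data.frame(layer)
    df$x <- p[, 1]
    df$y <- p[, 2]
    df$z <- p[, 3] + k * sym$rise
    df$chain <- labels[k + 1L]
    df$layer <- k
    df
  })
  atomic_model(do.call(rbind, out))
}

#' Estimate helical symmetry from an atomic model
#'
#' Recovers the screw operation relating consecutive layers of a stack.
#' For each consecutive chain pair the optimal rigid superposition
#' (Kabsch) of chain i onto chain i+1 is computed over their matched
#' atoms; the rotation is decomposed into an angle about the rotation
#' axis and the translation component along it. The axis is oriented so
#' the rise is positive; the twist sign then encodes handedness by the
#' right-hand rule (negative = left-handed). Results are averaged over
#' pairs.
#'
#' For a pure translation (twist numerically 0 within `tol_deg`) the
#' axis is taken along the translation and the twist reported as 0
#' (outside the `helical_symmetry` invariant; returned as a plain list).
#'
#' @param model an [atomic_model()] with >= 2 chains; consecutive chains
#'   (in `layer` order) must share matched atom sets (same `elety`/
#'   `resno` labels).
#' @param tol_deg rotation angle below which the pair is treated as a
#'   pure translation (default 1e-6 degrees).
#' @return list with `rise` (Angstrom), `twist` (signed degrees),
#'   `rmsd` (mean residual RMSD of the pair superpositions, Angstrom),
#'   `axis` (unit 3-vector), `n_pairs`.
#' @export
estimate_symmetry <- function(model, tol_deg = 1e-6) {
  chains <- unique(model$chain[order(model$layer)])
  if (length(chains) < 2) stop("estimate_symmetry: need >= 2 chains")
  pair_stats <- lapply(seq_len(length(chains) - 1L), function(i) {
    a <- model_subset(model, model$chain == chains[i])
    b <- model_subset(model, model$chain == chains[i + 1L])
    key_a <- paste(a$resno, a$elety)
    key_b <- paste(b$resno, b$elety)
    common <- intersect(key_a, key_b)
    if (length(common) < 3 || length(key_a) != length(key_b)) {
      stop("estimate_symmetry: unmatched atom sets between chains ",
           chains[i], " and ", chains[i + 1L])
    }
    xa <- coords(a)[match(common, key_a), , drop = FALSE]
    xb <- coords(b)[match(common, key_b), , drop = FALSE]
    k <- kabsch(xa, xb)
    # rotation angle and axis of R (y ~ x R + t; points transform by R^T
    # acting on column vectors, same axis/angle magnitude)
    R <- k$R
    cos_th <- (sum(diag(R)) - 1) / 2
    cos_th <- max(-1, min(1, cos_th))
    theta <- acos(cos_th)
    if (theta * 180 / pi < tol_deg) {
      u <- unit(k$t)
      return(list(rise = vnorm(k$t), twist = 0, rmsd = k$rmsd, axis = u))
    }
    # axis from the skew-symmetric part (row-vector convention:
    # for y = x %*% R, the rotation of column vectors is t(R))
    Rt <- t(R)
    u <- c(Rt[3, 2] - Rt[2, 3], Rt[1, 3] - Rt[3, 1], Rt[2, 1] - Rt[1, 2])
    if (vnorm(u) < 1e-12) {
      # theta ~ pi: axis from R + I
      M <- Rt + diag(3)
      u <- M[, which.max(colSums(M^2))]
    }
    u <- unit(u)  # right-hand rule: rotation by +theta about u
    rise <- sum(k$t * u)
    if (rise < 0) {
      u <- -u
      rise <- -rise
      theta <- -theta
    }
    list(rise = rise, twist = theta * 180 / pi, rmsd = k$rmsd, axis = u)
  })
  rise <- mean(vapply(pair_stats, `[[`, 0, "rise"))
  twist <- mean(vapply(pair_stats, `[[`, 0, "twist"))
  rmsd <- mean(vapply(pair_stats, `[[`, 0, "rmsd"))
  axis <- unit(colMeans(do.call(rbind, lapply(pair_stats, `[[`, "axis"))))
  list(rise = rise, twist = twist, rmsd = rmsd, axis = axis,
       n_pairs = length(pair_stats))
}

#' Axial height span of one chain
#'
#' The height change of the polypeptide chain along the fibril main axis:
#' max minus min C-alpha axial coordinate within the chain. A flat layer
#' spans 0; interdigitated fibril folds span several Angstrom.
#'
#' @param model an [atomic_model()].
#' @param chain chain label.
#' @param axis unit 3-vector giving the helix axis (default z; pass the
#'   `axis` from [estimate_symmetry()] for imported deposits).
#' @return span in Angstrom.
#' @export
axial_height_span <- function(model, chain, axis = c(0, 0, 1)) {
  sel <- model$chain == chain & model$elety == "CA"
  if (!any(sel)) stop("axial_height_span: no CA atoms in chain ", chain)
  h <- coords(model_subset(model, sel)) %*% unit(axis)
  max(h) - min(h)
}

#' Cross-sectional width of a model
#'
#' Maximal extent of the projection of the model onto the plane
#' perpendicular to the helix axis. Two modes: `"center"` measures the
#' maximal pairwise distance between atom centres; `"surface"` adds both
#' atoms' van der Waals radii, approximating the width a density map or
#' stain envelope would show.
#'
#' @param model an [atomic_model()].
#' @param axis unit helix-axis vector (default z).
#' @param mode `"center"` or `"surface"`.
#' @return width in Angstrom (0 for a single atom in center mode).
#' @export
measure_width <- function(model, axis = c(0, 0, 1), mode = c("center", "surface")) {
  mode <- match.arg(mode)
  if (nrow(model) == 0) stop("measure_width: empty model")
  u <- unit(axis)
  xyz <- coords(model)
  proj <- xyz - (xyz %*% u) %*% t(u)
  if (nrow(proj) == 1) {
    return(if (mode == "surface") 2 * vdw_radius(model$elesy) else 0)
  }
  d <- as.matrix(dist(proj))
  if (mode == "surface") {
    r <- vdw_radius(model$elesy)
    d <- d + outer(r, r, "+")
    diag(d) <- 0
  }
  max(d)
}

#' Map inter-layer residue contacts
#'
#' Finds all residue pairs whose minimum heavy-atom distance is within
#' `cutoff`, annotated by layer offset (canonicalized to >= 0). A salt
#' bridge is flagged when an Arg/Lys side-chain nitrogen and an Asp/Glu
#' side-chain oxygen are within `salt_bridge_cutoff`.
#'
#' @param model an [atomic_model()] with >= 2 layers.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param salt_bridge_cutoff Angstrom (default 4.0).
#' @param max_offset largest layer offset examined (default 2; fibril
#'   contacts rarely extend beyond the next layer).
#' @return data frame (`contact_map`): `resno_a`, `resid_a`, `resno_b`,
#'   `resid_b`, `offset`, `min_dist`, `salt_bridge`.
#' @export
interlayer_contacts <- function(model, cutoff = 4.5, salt_bridge_cutoff = 4.0,
                                max_offset = 2L) {
  if (cutoff <= 0) stop("interlayer_contacts: cutoff must be > 0")
  layers <- sort(unique(model$layer))
  if (length(layers) < 2) stop("interlayer_contacts: need >= 2 layers")
  heavy <- model_subset(model, model$elesy != "H")
  basic_n <- heavy$resid %in% c("ARG", "LYS") &
    heavy$elesy == "N" & !(heavy$elety %in% c("N"))
  acidic_o <- heavy$resid %in% c("ASP", "GLU") &
    heavy$elesy == "O" & !(heavy$elety %in% c("O", "OXT"))
  rows <- list()
  for (i in seq_along(layers)) {
    for (off in 0:max_offset) {
      j <- i + off
      if (j > length(layers)) next
      ai <- which(heavy$layer == layers[i])
      aj <- which(heavy$layer == layers[j])
      d <- sqrt(outer(heavy$x[ai], heavy$x[aj], "-")^2 +
                outer(heavy$y[ai], heavy$y[aj], "-")^2 +
                outer(heavy$z[ai], heavy$z[aj], "-")^2)
      near <- which(d <= cutoff, arr.ind = TRUE)
      if (nrow(near) == 0) next
      ra <- heavy$resno[ai[near[, 1]]]
      rb <- heavy$resno[aj[near[, 2]]]
      if (off == 0) {
        keep <- ra < rb  # skip self and double-counted intra-layer pairs
        near <- near[keep, , drop = FALSE]
        ra <- ra[keep]
        rb <- rb[keep]
        if (nrow(near) == 0) next
      }
      key <- paste(ra, rb)
      sb_atom <- (basic_n[ai[near[, 1]]] & acidic_o[aj[near[, 2]]] |
                  acidic_o[ai[near[, 1]]] & basic_n[aj[near[, 2]]]) &
        d[near] <= salt_bridge_cutoff
      agg <- data.frame(
        resno_a = ra, resno_b = rb, dist = d[near], sb = sb_atom)
      agg <- do.call(rbind, lapply(split(agg, key), function(g) {
        data.frame(resno_a = g$resno_a[1], resno_b = g$resno_b[1],
                   offset = off, min_dist = min(g$dist),
                   salt_bridge = any(g$sb))
      }))
      rows[[length(rows) + 1L]] <- agg
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(resno_a = integer(), resid_a = character(),
                      resno_b = integer(), resid_b = character(),
                      offset = integer(), min_dist = numeric(),
                      salt_bridge = logical())
  } else {
    out <- do.call(rbind, rows)
    # aggregate over layer pairs sharing the same offset
    key <- paste(out$resno_a, out$resno_b, out$offset)
    out <- do.call(rbind, lapply(split(out, key), function(g) {
      data.frame(resno_a = g$resno_a[1], resno_b = g$resno_b[1],
                 offset = g$offset[1], min_dist = min(g$min_dist),
                 salt_bridge = any(g$salt_bridge))
    }))
    res_name <- function(rn) {
      model$resid[match(rn, model$resno)]
    }
    out$resid_a <- res_name(out$resno_a)
    out$resid_b <- res_name(out$resno_b)
    out <- out[order(out$offset, out$resno_a, out$resno_b),
               c("resno_a", "resid_a", "resno_b", "resid_b",
                 "offset", "min_dist", "salt_bridge")]
    rownames(out) <- NULL
  }
  class(out) <- c("contact_map", "data.frame")
  out
}
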