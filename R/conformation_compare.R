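# Native-versus-fibril conformational comparison: dihedral-based strand
# assignment, strand-registry overlap, the disulfide-anchored rotational
# switch, and disulfide geometry.

# default beta region of the Ramachandran plot used by the strand
# heuristic; configurable because assignment conventions differ.
beta_region_default <- list(phi = c(-180, -45),
                            psi_main = c(45, 180),
                            psi_wrap = c(-180, -170))

in_beta_region <- function(phi, psi, region = beta_region_default) {
  !is.na(phi) & !is.na(psi) &
    phi >= region$phi[1] & phi <= region$phi[2] &
    ((psi >= region$psi_main[1] & psi <= region$psi_main[2]) |
     (psi >= region$psi_wrap[1] & psi <= region$psi_wrap[2]))
}

# per-residue backbone phi/psi for one chain; NA where atoms are missing
backbone_dihedrals <- function(structure, chain) {
  sub <- model_subset(structure, structure$chain == chain &
                        structure$elety %in% c("N", "CA", "C"))
  resnos <- sort(unique(sub$resno))
  get <- function(rn, name) {
    i <- which(sub$resno == rn & sub$elety == name)
    if (length(i) == 0) return(NULL)
    c(sub$x[i[1]], sub$y[i[1]], sub$z[i[1]])
  }
  phi <- psi <- rep(NA_real_, length(resnos))
  for (k in seq_along(resnos)) {
    rn <- resnos[k]
    n_i <- get(rn, "N"); ca_i <- get(rn, "CA"); c_i <- get(rn, "C")
    if (is.null(n_i) || is.null(ca_i) || is.null(c_i)) next
    if ((rn - 1) %in% resnos) {
      c_prev <- get(rn - 1, "C")
      if (!is.null(c_prev)) phi[k] <- dihedral(c_prev, n_i, ca_i, c_i)
    }
    if ((rn + 1) %in% resnos) {
      n_next <- get(rn + 1, "N")
      if (!is.null(n_next)) psi[k] <- dihedral(n_i, ca_i, c_i, n_next)
    }
  }
  data.frame(resno = resnos, phi = phi, psi = psi)
}

#' Assign extended (beta) strand segments from backbone dihedrals
#'
#' Maximal runs (length >= 2) of consecutive residues whose backbone
#' phi/psi fall in a documented beta region of the Ramachandran plot
#' (default: phi in \[-180, -45\], psi in \[45, 180\] or \[-180, -170\]).
#' Residues with missing backbone atoms are skipped with a warning.
#' Chain-terminal residues lack one dihedral and are not assignable.
#'
#' @param structure an [atomic_model()].
#' @param chain chain label (default first chain).
#' @param region beta-region definition (see source for the default).
#' @return data frame of `strand_segment`s: `start`, `end` (inclusive
#'   residue numbers), `length`.
#' @export
assign_extended_strands <- function(structure, chain = NULL,
                                    region = beta_region_default) {
  if (is.null(chain)) chain <- structure$chain[1]
  dih <- backbone_dihedrals(structure, chain)
  incomplete <- is.na(dih$phi) & is.na(dih$psi) &
    !dih$resno %in% range(dih$resno)
  if (any(incomplete)) {
    warning("assign_extended_strands: residues with missing backbone ",
            "atoms skipped: ", paste(dih$resno[incomplete], collapse = ", "))
  }
  beta <- in_beta_region(dih$phi, dih$psi, region)
  segs <- list()
  r <- rle(beta)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= 2) {
      # runs must also be consecutive in residue numbering
      rn <- dih$resno[starts[k]:ends[k]]
      brk <- c(0L, which(diff(rn) != 1L), length(rn))
      for (b in seq_len(length(brk) - 1L)) {
        piece <- rn[(brk[b] + 1L):brk[b + 1L]]
        if (length(piece) >= 2) {
          segs[[length(segs) + 1L]] <- data.frame(
            start = min(piece), end = max(piece), length = length(piece))
        }
      }
    }
  }
  if (length(segs) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  out <- do.call(rbind, segs)
  out[order(out$start), , drop = FALSE]
}

segment_coverage <- function(segments) {
  if (nrow(segments) == 0) return(integer(0))
  sort(unique(unlist(mapply(seq, segments$start, segments$end,
                            SIMPLIFY = FALSE))))
}

#' Residue-level overlap between two strand assignments
#'
#' @param segments_a,segments_b strand segment data frames (`start`,
#'   `end`) on the same residue numbering.
#' @return list with `jaccard` (|intersection| / |union| of covered
#'   residues; 1 if both empty), `shared`, `only_a`, `only_b` (integer
#'   residue vectors).
#' @export
strand_registry_overlap <- function(segments_a, segments_b) {
  a <- segment_coverage(segments_a)
  b <- segment_coverage(segments_b)
  un <- union(a, b)
  list(jaccard = if (length(un) == 0) 1 else
         length(intersect(a, b)) / length(un),
       shared = intersect(a, b),
       only_a = setdiff(a, b),
       only_b = setdiff(b, a))
}

# principal N->C direction of a run of CA atoms
segment_direction <- function(structure, chain, range) {
  sel <- structure$chain == chain & structure$elety == "CA" &
    structure$resno >= range[1] & structure$resno <= range[2]
  sub <- model_subset(structure, sel)
  sub <- sub[order(sub$resno), ]
  missing <- setdiff(range[1]:range[2], sub$resno)
  if (length(missing) > 0) {
    stop("segment ", range[1], "-", range[2],
         ": unresolved residues ", paste(missing, collapse = ", "))
  }
  if (nrow(sub) < 3) stop("segment must span >= 3 resolved residues")
  xyz <- coords(sub)
  xc <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(xc)$v[, 1]
  # orient N -> C
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * v) < 0) v <- -v
  unit(v)
}

#' Angle between two chain segments
#'
#' The angle (degrees, in \[0, 180\]) between the principal C-alpha
#' directions of two residue ranges, each oriented N-terminus to
#' C-terminus. Near 0 the segments run parallel, near 180 antiparallel.
#'
#' @param structure an [atomic_model()].
#' @param range_a,range_b two-element residue ranges (inclusive,
#'   length >= 3 resolved residues each).
#' @param chain chain label (default first chain).
#' @return angle in degrees.
#' @export
relative_orientation <- function(structure, range_a, range_b, chain = NULL) {
  if (is.null(chain)) chain <- structure$chain[1]
  va <- segment_direction(structure, chain, range_a)
  vb <- segment_direction(structure, chain, range_b)
  acos(max(-1, min(1, sum(va * vb)))) * 180 / pi
}

#' Native-versus-fibril rotational switch report
#'
#' Quantifies the conformational switch of the two disulfide-flanking
#' segments (defaults 16-23 and 86-93) between two structures: in each
#' structure the angle between the segments' N-to-C directions is
#' computed and classified parallel (< 90 degrees) or antiparallel
#' (> 90 degrees); the switch flag is set when the classifications
#' differ. In the light-chain system this is the ~180-degree rotation
#' around the Cys22-Cys89 disulfide that distinguishes the fibril fold
#' from the natively folded V-domain.
#'
#' @param native,fibril [atomic_model()]s with both ranges resolved.
#' @param range_a,range_b residue ranges (defaults 16-23 and 86-93).
#' @param chain_native,chain_fibril chain labels (default first chain of
#'   each model).
#' @return a `switch_report` list: `angle_native`, `angle_fibril`
#'   (degrees), `class_native`, `class_fibril`
#'   (`"parallel"`/`"antiparallel"`), `switch_detected`.
#' @export
switch_report <- function(native, fibril, range_a = c(16, 23),
                          range_b = c(86, 93), chain_native = NULL,
                          chain_fibril = NULL) {
  an <- relative_orientation(native, range_a, range_b, chain_native)
  af <- relative_orientation(fibril, range_a, range_b, chain_fibril)
  cls <- function(a) if (a < 90) "parallel" else "antiparallel"
  structure(list(angle_native = an, angle_fibril = af,
                 class_native = cls(an), class_fibril = cls(af),
                 switch_detected = cls(an) != cls(af)),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf(
    "rotational switch: native %.1f deg (%s) vs fibril %.1f deg (%s) -> %s\n",
    x$angle_native, x$class_native, x$angle_fibril, x$class_fibril,
    if (x$switch_detected) "SWITCH" else "no switch"))
  invisible(x)
}

#' Disulfide bond geometry
#'
#' Measures the S-gamma to S-gamma distance between two cysteines and
#' calls the pair bonded when the distance falls in \[1.8, 2.5\] Angstrom,
#' a window around the 2.05 A canonical S-S bond length.
#'
#' @param structure an [atomic_model()].
#' @param res_a,res_b cysteine residue numbers (defaults 22 and 89).
#' @param chain chain label (default first chain).
#' @param window bonded-distance window (Angstrom).
#' @return list with `distance` (Angstrom) and `bonded` (logical).
#' @export
disulfide_geometry <- function(structure, res_a = 22, res_b = 89,
                               chain = NULL, window = c(1.8, 2.5)) {
  if (is.null(chain)) chain <- structure$chain[1]
  sg <- function(rn) {
    sel <- structure$chain == chain & structure$resno == rn
    if (!any(sel)) stop("disulfide_geometry: residue ", rn, " not found")
    if (!all(structure$resid[sel] == "CYS")) {
      stop("disulfide_geometry: residue ", rn, " is not a cysteine")
    }
    i <- which(sel & structure$elety == "SG")
    if (length(i) == 0) {
      stop("disulfide_geometry: residue ", rn, " has no SG atom")
    }
    c(structure$x[i[1]], structure$y[i[1]], structure$z[i[1]])
  }
  d <- vnorm(sg(res_a) - sg(res_b))
  list(distance = d, bonded = d >= window[1] && d <= window[2])
}
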