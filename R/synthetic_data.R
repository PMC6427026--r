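# Synthetic-data generators: every input the analysis stages need can be
# produced here, deterministically under explicit seeds, so the whole
# pipeline runs offline at desk scale.

#' Worm-like-chain simulation parameters
#'
#' @param persistence_length persistence length P in micrometres (> 0).
#' @param step arc-length increment in micrometres; must satisfy
#'   `0 < step <= total_length` and `step <= persistence_length / 50`
#'   (discretization validity: the Gaussian tangent-increment construction
#'   is only a faithful WLC when each step turns the tangent by a small
#'   angle).
#' @param total_length contour length in micrometres.
#' @param seed integer RNG seed; all generators take explicit seeds.
#' @return a `wlc_params` list.
#' @seealso [generate_wlc_trace()]
#' @export
wlc_params <- function(persistence_length, step, total_length, seed = 42L) {
  if (!is.numeric(persistence_length) || persistence_length <= 0) {
    stop("wlc_params: persistence_length must be > 0")
  }
  if (!is.numeric(step) || step <= 0 || step > total_length) {
    stop("wlc_params: need 0 < step <= total_length")
  }
  if (step > persistence_length / 50) {
    stop("wlc_params: step must be <= persistence_length / 50 ",
         "(discretization validity)")
  }
  structure(list(persistence_length = persistence_length, step = step,
                 total_length = total_length, seed = as.integer(seed)),
            class = "wlc_params")
}

#' Generate one 2D worm-like-chain fibril trace
#'
#' Simulates a discretized two-dimensional (in-plane equilibrated)
#' worm-like chain: successive tangent angles differ by independent
#' Gaussian increments of variance `step / persistence_length` (radians
#' squared), which gives the tangent autocorrelation
#' `<cos(theta(s) - theta(0))> = exp(-s / (2 P))` — the kernel underlying
#' the surface-equilibrated mean squared end-to-end distance
#' `<D^2> = 4 P L [1 - (2P/L)(1 - exp(-L/2P))]`. The 2D form is the one
#' appropriate for fibrils that equilibrate on a support film before
#' imaging, which is how fibril persistence lengths are measured from
#' negative-stain micrographs.
#'
#' @param params a [wlc_params()] object.
#' @param fibril_id label attached to the trace.
#' @return a `fibril_trace`: data frame with columns `x_nm`, `y_nm`
#'   (vertex coordinates, nanometres) and attribute `fibril_id`. The trace
#'   has `round(total_length / step)` segments of exactly `step`
#'   micrometres each, so its contour length is `n_segments * step`.
#' @examples
#' tr <- generate_wlc_trace(wlc_params(6.7, 0.02, 3, seed = 1))
#' measure_trace(tr)
#' @export
generate_wlc_trace <- function(params, fibril_id = "fibril_1") {
  if (!inherits(params, "wlc_params")) params <- do.call(wlc_params, params)
  n_seg <- max(1L, as.integer(round(params$total_length / params$step)))
  set.seed(params$seed)
  theta0 <- runif(1, 0, 2 * pi)
  dtheta <- rnorm(n_seg - 1L, mean = 0,
                  sd = sqrt(params$step / params$persistence_length))
  theta <- theta0 + c(0, cumsum(dtheta))
  step_nm <- params$step * 1000
  x <- c(0, cumsum(step_nm * cos(theta)))
  y <- c(0, cumsum(step_nm * sin(theta)))
  fibril_trace(x, y, fibril_id = fibril_id)
}

#' Construct a fibril trace from vertex coordinates
#'
#' @param x_nm,y_nm vertex coordinates in nanometres (>= 2 vertices,
#'   consecutive vertices distinct).
#' @param fibril_id label.
#' @return a `fibril_trace` data frame.
#' @export
fibril_trace <- function(x_nm, y_nm, fibril_id = "fibril_1") {
  if (length(x_nm) < 2 || length(x_nm) != length(y_nm)) {
    stop("fibril_trace: need >= 2 (x, y) vertices")
  }
  seg <- sqrt(diff(x_nm)^2 + diff(y_nm)^2)
  if (any(seg == 0)) stop("fibril_trace: consecutive vertices must be distinct")
  structure(data.frame(x_nm = x_nm, y_nm = y_nm),
            fibril_id = fibril_id, class = c("fibril_trace", "data.frame"))
}

#' Generate an ensemble of worm-like-chain traces
#'
#' Emulates a micrograph survey of many fibrils: `n` traces at a common
#' persistence length, with contour lengths drawn uniformly from
#' `length_range`. The published measurement this mirrors used 124
#' well-resolved fibrils.
#'
#' @param persistence_length P in micrometres.
#' @param n number of traces (>= 2; the downstream fit needs >= 2 points).
#' @param length_range two-element numeric, contour-length range in
#'   micrometres (positive, ordered; a degenerate range `c(a, a)` is
#'   allowed).
#' @param step arc-length increment in micrometres.
#' @param seed integer seed; the ensemble is reproducible under it.
#' @return list of `fibril_trace` objects.
#' @export
generate_trace_ensemble <- function(persistence_length, n,
                                    length_range = c(1, 8),
                                    step = 0.02, seed = 42L) {
  if (n < 2) stop("generate_trace_ensemble: n must be >= 2")
  if (length(length_range) != 2 || any(length_range <= 0) ||
      length_range[1] > length_range[2]) {
    stop("generate_trace_ensemble: length_range must be positive and ordered")
  }
  set.seed(seed)
  lens <- runif(n, length_range[1], length_range[2])
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    generate_wlc_trace(
      wlc_params(persistence_length, step, lens[i], seed = sub_seeds[i]),
      fibril_id = sprintf("fibril_%03d", i))
  })
}

#' Generate an idealized flat protomer layer
#'
#' Builds one fibril layer as a flat (constant axial coordinate, z = 0)
#' backbone polyline folded into a U-shaped beta-arch: two strand-like
#' legs joined by a wide turn, with consecutive C-alpha spacing
#' approximately `spacing`. It is an idealized stand-in for one molecular
#' layer of a cross-beta stack, flat by construction so that axial height
#' measurements and screw-stacking round trips have exact expectations.
#'
#' @param n_residues number of residues (>= 4).
#' @param spacing target consecutive C-alpha distance in Angstrom
#'   (default 3.8, extended-strand like).
#' @param chain chain label.
#' @return an [atomic_model()] with N, CA, C atoms per residue, all at
#'   z = 0, `layer = 0`.
#' @export
generate_beta_arch_layer <- function(n_residues, spacing = 3.8, chain = "A") {
  if (n_residues < 4) stop("generate_beta_arch_layer: n_residues must be >= 4")
  # U-shape with exact consecutive CA spacing: two straight legs joined
  # by a semicircular turn whose chords all equal `spacing`. The turn is
  # divided into n_turn equal chords, so its radius follows from
  # chord = 2 R sin(pi / (2 n_turn)).
  n_turn <- min(6L, n_residues - 2L)
  turn_radius <- spacing / (2 * sin(pi / (2 * n_turn)))
  n_interior <- n_turn - 1L  # turn points strictly between the two legs
  n_leg1 <- ceiling((n_residues - n_interior) / 2)
  n_leg2 <- n_residues - n_interior - n_leg1
  ca <- matrix(NA_real_, n_residues, 2)
  i <- 0L
  for (k in seq_len(n_leg1)) {
    i <- i + 1L
    ca[i, ] <- c((k - 1L) * spacing, 0)
  }
  x0 <- (n_leg1 - 1L) * spacing  # leg1 end, on the turn circle
  for (j in seq_len(n_interior)) {
    i <- i + 1L
    phi <- -pi / 2 + j * pi / n_turn
    ca[i, ] <- c(x0 + turn_radius * cos(phi),
                 turn_radius + turn_radius * sin(phi))
  }
  for (k in seq_len(n_leg2)) {
    i <- i + 1L
    ca[i, ] <- c(x0 - (k - 1L) * spacing, 2 * turn_radius)
  }
  # backbone N and C flanking each CA along the local path direction
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(r) {
    p <- ca[r, ]
    dir_prev <- if (r > 1) p - ca[r - 1L, ] else ca[r + 1L, ] - p
    dir_next <- if (r < n_residues) ca[r + 1L, ] - p else p - ca[r - 1L, ]
    dn <- dir_prev / sqrt(sum(dir_prev^2))
    dc <- dir_next / sqrt(sum(dir_next^2))
    data.frame(
      elety = c("N", "CA", "C"),
      resid = "ALA",
      resno = r,
      chain = chain,
      x = c(p[1] - 1.2 * dn[1], p[1], p[1] + 1.2 * dc[1]),
      y = c(p[2] - 1.2 * dn[2], p[2], p[2] + 1.2 * dc[2]),
      z = 0,
      stringsAsFactors = FALSE)
  }))
  atomic_model(atoms)
}

#' Cavity phantom specification
#'
#' @param void_radius radius (Angstrom) of the spherical interior void the
#'   phantom encloses; `0` produces a solid ball with no void.
#' @param shell_thickness radial thickness of the atom shell (Angstrom);
#'   must be at least twice the van der Waals radius of `atom_element` so
#'   the shell can seal.
#' @param atom_spacing spacing between shell pseudo-atoms (Angstrom);
#'   must be <= 1.5 so a 1.4 A water probe cannot leak between atoms.
#' @param atom_element element symbol of the pseudo-atoms ("C", "N", "O",
#'   "S"); also sets the pseudo-residue chemistry (O -> Ser-like polar
#'   hydroxyl atoms, C -> Leu-like apolar carbons, ...).
#' @param probe probe radius (Angstrom) the phantom is calibrated for: the
#'   innermost atom centres sit at `void_radius + vdW + probe` from the
#'   void centre, so that cavity detection with this probe recovers a free
#'   void of radius `void_radius` (analytic volume `4/3 pi r^3`).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(void_radius, shell_thickness = 4,
                         atom_spacing = 1.0, atom_element = "C",
                         probe = 1.4) {
  if (void_radius < 0) stop("phantom_spec: void_radius must be >= 0")
  if (atom_spacing > 1.5) {
    stop("phantom_spec: atom_spacing > 1.5 A cannot seal against a 1.4 A probe")
  }
  if (shell_thickness < 2 * vdw_radius(atom_element)) {
    stop("phantom_spec: shell_thickness must be >= 2 x vdW radius")
  }
  structure(list(void_radius = void_radius,
                 shell_thickness = shell_thickness,
                 atom_spacing = atom_spacing,
                 atom_element = atom_element,
                 probe = probe),
            class = "phantom_spec")
}

# near-uniform points on a sphere of radius r (Fibonacci lattice)
fibonacci_sphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = r * sin(phi) * cos(theta),
        y = r * sin(phi) * sin(theta),
        z = r * cos(phi))
}

#' Generate a cavity phantom model
#'
#' Builds a closed spherical shell of pseudo-atoms enclosing one interior
#' void of known analytic volume — the ground-truth object for validating
#' cavity detection. Optionally bores a cylindrical channel through the
#' shell (along +z), which connects the interior to the exterior so that
#' no sealed cavity remains.
#'
#' @param spec a [phantom_spec()].
#' @param channel_radius radius (Angstrom) of a channel bored along the
#'   +z axis; 0 (default) leaves the shell sealed.
#' @return an [atomic_model()] of pseudo-atoms.
#' @export
generate_cavity_phantom <- function(spec, channel_radius = 0) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  rv <- vdw_radius(spec$atom_element)
  r_in <- if (spec$void_radius > 0) spec$void_radius + rv + spec$probe else 0
  radii <- if (r_in > 0) {
    seq(r_in, r_in + spec$shell_thickness, by = spec$atom_spacing)
  } else {
    seq(0, spec$shell_thickness, by = spec$atom_spacing)
  }
  pts <- do.call(rbind, lapply(radii, function(r) {
    if (r == 0) return(matrix(0, 1, 3, dimnames = list(NULL, c("x", "y", "z"))))
    n <- max(12L, as.integer(ceiling(4 * pi * r^2 / spec$atom_spacing^2)))
    fibonacci_sphere(n, r)
  }))
  if (channel_radius > 0) {
    keep <- !(sqrt(pts[, 1]^2 + pts[, 2]^2) < channel_radius & pts[, 3] > 0)
    pts <- pts[keep, , drop = FALSE]
  }
  chem <- switch(toupper(spec$atom_element),
                 O = list(elety = "OG",  resid = "SER"),
                 N = list(elety = "ND2", resid = "ASN"),
                 S = list(elety = "SG",  resid = "CYS"),
                 list(elety = "CD1", resid = "LEU"))
  atomic_model(data.frame(
    elety = chem$elety, resid = chem$resid,
    resno = seq_len(nrow(pts)), chain = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    elesy = toupper(spec$atom_element),
    stringsAsFactors = FALSE))
}

# amino-acid code tables
aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Parse mutation shorthand
#'
#' Accepts `"Ser25Arg"` / `"S25R"` style strings and returns a data frame
#' with columns `from`, `pos`, `to` (one-letter codes, 1-based mature
#' numbering).
#'
#' @param x character vector of substitutions.
#' @export
parse_mutations <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$", x))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("parse_mutations: unparseable: ",
                     paste(x[bad], collapse = ", "))
  to1 <- function(code) {
    out <- ifelse(nchar(code) == 1, toupper(code),
                  aa3to1[toupper(code)])
    if (anyNA(out)) stop("parse_mutations: unknown residue code")
    out
  }
  data.frame(
    from = to1(vapply(m, `[`, "", 2L)),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    to = to1(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE)
}

#' Apply point substitutions to a sequence
#'
#' Applies substitutions `(from, pos, to)` to an amino-acid string, with a
#' consistency guard: each `from` must match the residue actually present
#' at `pos` (1-based mature-chain numbering). This guard is what catches
#' numbering-convention mistakes between sequence sources.
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param mutations data frame with columns `from`, `pos`, `to`, or a
#'   character vector of `"Ser25Arg"`-style shorthand.
#' @return the mutated sequence (same length).
#' @examples
#' apply_mutations("GCAT", data.frame(from = "C", pos = 2, to = "W"))
#' @export
apply_mutations <- function(sequence, mutations) {
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  if (nrow(mutations) == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (any(mutations$pos < 1 | mutations$pos > length(chars))) {
    stop("apply_mutations: position outside sequence")
  }
  have <- chars[mutations$pos]
  bad <- have != mutations$from
  if (any(bad)) {
    stop("apply_mutations: residue mismatch at position ",
         paste(mutations$pos[bad], collapse = ", "),
         " (found ", paste(have[bad], collapse = ", "),
         ", expected ", paste(mutations$from[bad], collapse = ", "), ")")
  }
  chars[mutations$pos] <- mutations$to
  paste(chars, collapse = "")
}

#' Synthetic germline-like lambda V_L template sequence
#'
#' A synthetic 110-residue lambda light-chain variable-domain-like
#' template used for testing and demonstration. It is NOT a patient or
#' database sequence: the true germline sequence behind the analysed
#' fibril is not published. The template is constructed to honor, at the
#' mature-chain positions the fibril study names, the stated residue
#' identities (e.g. Gly15, Cys22, Ser25, Asn35, Asn53, Ile76, Glu84,
#' Asp86, Cys89, Asp94, Gly98, Thr105), so that the ten patient
#' substitutions apply cleanly and structural landmarks (the Cys22-Cys89
#' disulfide, the Gly15-Thr105 ordered core) fall at the right positions.
#'
#' @return one-letter amino-acid string of length 110.
#' @export
germline_template <- function() {
  paste0(
    "QSVLTQPPSA", "SGTPGQRVTI",  #   1-20
    "SCSGSSSNIG", "SNTVNWYQQL",  #  21-40
    "PGTAPKLLIY", "SNNQRPSGVP",  #  41-60
    "DRFSGSKSGT", "SAKLAISGLQ",  #  61-80
    "SEDEADYYCA", "AWDDSLNGWV",  #  81-100
    "FGGGTKLTVL")                # 101-110
}

#' The ten patient substitutions relative to the germline template
#'
#' @return data frame with columns `from`, `pos`, `to`.
#' @export
patient_mutations <- function() {
  parse_mutations(c("Ser25Arg", "Ser31Arg", "Thr33Leu", "Asn35Lys",
                    "Leu40Phe", "Asn53Asp", "Ile76Val", "Asp94Ala",
                    "Ser95Thr", "Gly98Ala"))
}

#' Synthetic patient-like sequence
#'
#' The [germline_template()] with [patient_mutations()] applied.
#' @return one-letter amino-acid string of length 110.
#' @export
patient_sequence <- function() {
  apply_mutations(germline_template(), patient_mutations())
}
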