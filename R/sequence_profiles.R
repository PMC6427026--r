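# Per-residue hydropathy, consensus amyloidogenicity scoring from five
# aggregation predictors, and germline-mutation listing/classification.

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector, one value per one-letter amino-acid code.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Aggrescan a4v aggregation-propensity scale
#'
#' Per-residue aggregation-propensity values (a4v: amino-acid aggregation
#' propensity derived from in vivo data), as published with the Aggrescan
#' method. Residues with values above the published hot-spot threshold
#' (-0.02) are aggregation prone.
#'
#' @return named numeric vector over the 20 amino acids.
#' @export
aggrescan_a4v <- function() {
  c(I =  1.822, F =  1.754, V =  1.594, L =  1.380, Y =  1.159,
    W =  1.037, M =  0.910, C =  0.604, A = -0.036, T = -0.159,
    S = -0.294, P = -0.334, G = -0.535, N = -0.713, H = -0.725,
    Q = -0.776, R = -1.240, E = -1.412, D = -1.836, K = -2.109)
}

seq_to_chars <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(chars, names(kyte_doolittle()))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  }
  chars
}

#' Sliding-window hydropathy profile
#'
#' Centred sliding-window mean of the Kyte-Doolittle hydropathy scale
#' (or any supplied per-residue scale); windows are truncated at the
#' termini so every residue gets a value.
#'
#' @param sequence amino-acid string.
#' @param window odd window size (default 1: per-residue values).
#' @param scale named per-residue scale (default [kyte_doolittle()]).
#' @return numeric vector, one value per residue.
#' @examples
#' hydropathy_profile("III", window = 1)
#' @export
hydropathy_profile <- function(sequence, window = 1L,
                               scale = kyte_doolittle()) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  if (window %% 2 == 0 || window < 1 || window > n) {
    stop("hydropathy_profile: window must be odd and <= sequence length")
  }
  vals <- unname(scale[chars])
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(vals[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Threshold-and-run scan of a per-residue scale
#'
#' Marks residues whose scale value passes a threshold in runs of at
#' least `min_run` consecutive residues — the rule used by
#' packing-density-style predictors (e.g. the published rule "value above
#' 21.4 for five consecutive residues") and, with `min_run = 1`, by
#' plain hot-spot thresholds.
#'
#' @param sequence amino-acid string.
#' @param scale named per-residue scale covering all residues in the
#'   sequence, or a numeric vector of per-position values of the same
#'   length as the sequence.
#' @param threshold numeric threshold (strict inequality).
#' @param min_run minimum run length (>= 1).
#' @param mode `"above"` (default) or `"below"`.
#' @param predictor name stored on the result.
#' @return a `predictor_hits` list: `predictor`, `positions` (sorted
#'   integer vector).
#' @export
scale_scan <- function(sequence, scale, threshold, min_run = 1L,
                       mode = c("above", "below"), predictor = "scan") {
  mode <- match.arg(mode)
  if (min_run < 1) stop("scale_scan: min_run must be >= 1")
  n <- nchar(sequence)
  if (!is.null(names(scale))) {
    vals <- unname(scale[seq_to_chars(sequence)])
    if (anyNA(vals)) stop("scale_scan: scale does not cover all residues")
  } else {
    if (length(scale) != n) {
      stop("scale_scan: per-position scale must match sequence length")
    }
    vals <- scale
  }
  pass <- if (mode == "above") vals > threshold else vals < threshold
  pass[is.na(pass)] <- FALSE
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- integer(0)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= min_run) {
      pos <- c(pos, starts[k]:ends[k])
    }
  }
  predictor_hits(predictor, pos, n)
}

#' Predictor hit set
#'
#' @param predictor predictor name.
#' @param positions integer positions marked as aggregation prone.
#' @param seq_length sequence length the positions refer to.
#' @return a `predictor_hits` list.
#' @export
predictor_hits <- function(predictor, positions, seq_length) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) > 0 &&
      (min(positions) < 1 || max(positions) > seq_length)) {
    stop("predictor_hits: positions outside sequence bounds")
  }
  structure(list(predictor = predictor, positions = positions,
                 seq_length = as.integer(seq_length)),
            class = "predictor_hits")
}

# per-predictor ingestion rules, as published with the consensus score:
# WALTZ and TANGO (beta aggregation) values strictly above 0.00 are hits;
# FoldAmyloid values above 21.4 in runs of >= 5 residues; Aggrescan
# values above -0.02; AmylPred rows carry a consensus hit flag.
predictor_rules <- list(
  WALTZ       = list(threshold = 0.00,  min_run = 1L, flag = FALSE),
  TANGO       = list(threshold = 0.00,  min_run = 1L, flag = FALSE),
  FoldAmyloid = list(threshold = 21.4,  min_run = 5L, flag = FALSE),
  Aggrescan   = list(threshold = -0.02, min_run = 1L, flag = FALSE),
  AmylPred    = list(threshold = NA,    min_run = 1L, flag = TRUE)
)

#' Names of the five consensus predictors
#' @return character vector.
#' @export
amyloid_predictors <- function() names(predictor_rules)

#' Parse an external aggregation-predictor output file
#'
#' Reads the documented TSV dialect — two tab-separated columns,
#' `position` and `value` (or `position` and 0/1 `hit` flag for the
#' AmylPred consensus) with an optional header line — and applies the
#' predictor's published hit rule (see [amyloid_predictors()] and the
#' rules in [scale_scan()]).
#'
#' @param file path to the TSV file.
#' @param predictor one of `"WALTZ"`, `"TANGO"`, `"FoldAmyloid"`,
#'   `"Aggrescan"`, `"AmylPred"`.
#' @param seq_length sequence length for bounds validation.
#' @return a [predictor_hits()] object.
#' @export
parse_predictor_output <- function(file, predictor, seq_length) {
  if (!predictor %in% names(predictor_rules)) {
    stop("parse_predictor_output: unknown predictor '", predictor, "'")
  }
  rule <- predictor_rules[[predictor]]
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("^[#a-zA-Z]", lines[1])) {
    lines <- lines[-1]  # header or comment
  }
  if (length(lines) == 0) {
    return(predictor_hits(predictor, integer(0), seq_length))
  }
  pos <- numeric(length(lines))
  val <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[\t ]+")[[1]]
    f <- f[nzchar(f)]
    p <- suppressWarnings(as.numeric(f[1]))
    v <- if (length(f) >= 2) suppressWarnings(as.numeric(f[2])) else NA
    if (length(f) < 2 || is.na(p) || is.na(v) || p != round(p)) {
      stop("parse_predictor_output: malformed row at line ", i, ": '",
           lines[i], "'")
    }
    pos[i] <- p
    val[i] <- v
  }
  if (any(pos < 1 | pos > seq_length)) {
    stop("parse_predictor_output: position beyond sequence length")
  }
  full <- rep(NA_real_, seq_length)
  full[pos] <- val
  if (rule$flag) {
    hits <- which(!is.na(full) & full != 0)
    if (rule$min_run > 1L) stop("unreachable")
    return(predictor_hits(predictor, hits, seq_length))
  }
  scan <- scale_scan(strrep("A", seq_length), scale = full,
                     threshold = rule$threshold, min_run = rule$min_run,
                     predictor = predictor)
  scan
}

#' Consensus amyloid score profile
#'
#' Per-residue count (0-5) of aggregation predictors marking the residue
#' as amyloidogenic: 0 means no program identifies it, 5 means all five
#' do. Requires exactly the five named predictors, each exactly once.
#'
#' @param hit_sets list of five [predictor_hits()] objects (WALTZ, TANGO,
#'   FoldAmyloid, Aggrescan, AmylPred, any order).
#' @param sequence the scored amino-acid string.
#' @return an `amyloid_score_profile`: data frame with `position`,
#'   `residue`, `score` (0-5) and `predictors` (comma-separated names of
#'   the programs hitting that residue).
#' @export
consensus_amyloid_score <- function(hit_sets, sequence) {
  names_seen <- vapply(hit_sets, `[[`, "", "predictor")
  if (!setequal(names_seen, amyloid_predictors()) ||
      anyDuplicated(names_seen)) {
    stop("consensus_amyloid_score: need exactly the five predictors ",
         paste(amyloid_predictors(), collapse = ", "), ", each once")
  }
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  score <- integer(n)
  who <- vector("list", n)
  for (hs in hit_sets) {
    if (length(hs$positions) > 0 && max(hs$positions) > n) {
      stop("consensus_amyloid_score: hits beyond sequence length")
    }
    score[hs$positions] <- score[hs$positions] + 1L
    for (p in hs$positions) who[[p]] <- c(who[[p]], hs$predictor)
  }
  out <- data.frame(
    position = seq_len(n), residue = chars, score = score,
    predictors = vapply(who, function(w) paste(sort(w), collapse = ","), ""),
    stringsAsFactors = FALSE)
  class(out) <- c("amyloid_score_profile", "data.frame")
  out
}

#' List substitutions between an aligned patient/germline pair
#'
#' @param patient_seq,germline_seq equal-length amino-acid strings on the
#'   same (mature, 1-based) numbering; alignment is the caller's
#'   responsibility.
#' @return data frame (`mutation_record`s), one row per differing
#'   position, ordered by position: `pos`, `germline`, `patient`.
#' @examples
#' list_mutations(patient_sequence(), germline_template())
#' @export
list_mutations <- function(patient_seq, germline_seq) {
  if (nchar(patient_seq) != nchar(germline_seq)) {
    stop("list_mutations: sequences must be aligned to equal length")
  }
  p <- seq_to_chars(patient_seq)
  g <- seq_to_chars(germline_seq)
  d <- which(p != g)
  data.frame(pos = d, germline = g[d], patient = p[d],
             stringsAsFactors = FALSE)
}

#' Extract the ordered fibril core of a sequence
#'
#' The structurally ordered segment of a fibril protein, by mature-chain
#' residue numbering (default 15-105, the Gly15-Thr105 core of the AL
#' fibril system this package models: 91 residues, with the first and
#' last ~12 residues of the chain conformationally disordered).
#'
#' @param sequence full mature-chain amino-acid string.
#' @param start,end inclusive residue numbers (defaults 15 and 105).
#' @return list with `start`, `end`, `length` and `sequence` (the core
#'   substring).
#' @export
ordered_core <- function(sequence, start = 15L, end = 105L) {
  if (start < 1 || end > nchar(sequence) || start > end) {
    stop("ordered_core: range outside sequence")
  }
  list(start = as.integer(start), end = as.integer(end),
       length = as.integer(end - start + 1L),
       sequence = substr(sequence, start, end))
}

# side-chain formal charge at pH 7
residue_charge <- function(aa1) {
  unname(c(D = -1, E = -1, K = 1, R = 1)[aa1]) -> ch
  ch[is.na(ch)] <- 0
  ch
}

#' Classify a germline mutation structurally
#'
#' Annotates one mutation record with: the side-chain formal-charge
#' change at pH 7 (germline vs patient residue), surface/buried state via
#' a neighbour-count burial proxy (heavy atoms within `burial_radius` of
#' the residue's C-beta — C-alpha for glycine; counts at or above
#' `burial_threshold` are "buried", a standard coordination-number proxy
#' for low solvent accessibility), CDR membership against supplied
#' ranges, and cavity lining against supplied lining residue sets.
#'
#' @param record one-row data frame with `pos`, `germline`, `patient`
#'   (as produced by [list_mutations()]).
#' @param structure an [atomic_model()] containing the residue (or
#'   `NULL`: burial is then `NA` with a warning).
#' @param cdr_ranges list of `c(start, end)` residue ranges (mature
#'   numbering) or `NULL`.
#' @param cavity_linings named list of integer residue-number vectors,
#'   one per cavity (e.g. from [cavity_polarity_report()]), or `NULL`.
#' @param chain chain label to annotate against (default first chain).
#' @param burial_radius neighbour-count radius in Angstrom (default 10).
#' @param burial_threshold neighbour count at/above which a residue is
#'   called buried (default 24).
#' @return the record with added columns `charge_germline`,
#'   `charge_patient`, `charge_change`, `buried`, `cdr`, `cavities`.
#' @export
classify_mutation <- function(record, structure = NULL, cdr_ranges = NULL,
                              cavity_linings = NULL, chain = NULL,
                              burial_radius = 10, burial_threshold = 24) {
  stopifnot(nrow(record) == 1)
  cg <- residue_charge(record$germline)
  cp <- residue_charge(record$patient)
  record$charge_germline <- cg
  record$charge_patient <- cp
  record$charge_change <- cp - cg
  buried <- NA
  if (!is.null(structure)) {
    if (is.null(chain)) chain <- structure$chain[1]
    res <- structure$chain == chain & structure$resno == record$pos
    if (!any(res)) {
      warning("classify_mutation: residue ", record$pos,
              " missing from structure; burial not annotated")
    } else {
      anchor_name <- if (any(structure$elety[res] == "CB")) "CB" else "CA"
      anchor <- which(res & structure$elety == anchor_name)[1]
      if (is.na(anchor)) {
        warning("classify_mutation: no CA/CB anchor for residue ",
                record$pos)
      } else {
        heavy <- structure$elesy != "H"
        d2 <- (structure$x - structure$x[anchor])^2 +
          (structure$y - structure$y[anchor])^2 +
          (structure$z - structure$z[anchor])^2
        own <- structure$chain == chain & structure$resno == record$pos
        nn <- sum(heavy & !own & d2 <= burial_radius^2)
        buried <- nn >= burial_threshold
      }
    }
  }
  record$buried <- buried
  record$cdr <- if (is.null(cdr_ranges)) NA else {
    any(vapply(cdr_ranges, function(r) {
      record$pos >= r[1] && record$pos <= r[2]
    }, logical(1)))
  }
  record$cavities <- if (is.null(cavity_linings)) NA_character_ else {
    inn <- names(cavity_linings)[vapply(cavity_linings, function(v) {
      record$pos %in% v
    }, logical(1))]
    paste(inn, collapse = ",")
  }
  record
}
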