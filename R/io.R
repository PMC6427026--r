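# Structure, sequence and trace I/O. Structure parsing is delegated to
# bio3d (PDB and mmCIF); traces travel as plain CSV.

#' Read an atomic model from PDB or mmCIF
#'
#' Parses the file with bio3d and returns an [atomic_model()]. Only ATOM/
#' HETATM records with coordinates are kept. When alternate locations are
#' present, the highest-occupancy altloc of each atom is kept (ties: the
#' first) and a message is emitted. Layer indices are assigned per chain
#' in order of appearance; re-derive the axis with [estimate_symmetry()]
#' for deposited fibril models.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @return an [atomic_model()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) {
      stop("read_structure: cannot parse '", path, "': ",
           conditionMessage(e))
    })
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("read_structure: no atoms in '", path, "'")
  }
  # altloc policy: keep the highest-occupancy altloc per atom site
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      occ <- at$o[idx]
      occ[is.na(occ)] <- 1
      idx[which.max(occ)]
    }))
    if (length(keep) < nrow(at)) {
      message("read_structure: kept highest-occupancy altloc for ",
              nrow(at) - length(keep), " duplicated atom site(s)")
    }
    at <- at[sort(keep), , drop = FALSE]
  }
  atomic_model(data.frame(
    elety = at$elety, resid = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    elesy = if (!is.null(at$elesy) && !all(is.na(at$elesy)) &&
                !all(at$elesy == "")) at$elesy else guess_element(at$elety),
    stringsAsFactors = FALSE))
}

#' Write an atomic model to PDB
#'
#' @param model an [atomic_model()].
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  xyz <- as.numeric(t(coords(model)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(model)),
                   resno = model$resno, resid = model$resid,
                   eleno = seq_len(nrow(model)), elety = model$elety,
                   chain = model$chain, elesy = model$elesy)
  invisible(path)
}

#' Write fibril traces to CSV
#'
#' Column layout: `fibril_id`, `vertex_index` (1-based), `x_nm`, `y_nm`.
#'
#' @param traces list of `fibril_trace` objects (or a single trace).
#' @param path output CSV path.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "fibril_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(fibril_id = attr(tr, "fibril_id"),
               vertex_index = seq_len(nrow(tr)),
               x_nm = tr$x_nm, y_nm = tr$y_nm,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fibril traces from CSV
#'
#' @param path CSV with columns `fibril_id`, `vertex_index`, `x_nm`,
#'   `y_nm` (see [write_traces()]).
#' @return list of `fibril_trace` objects, in file order.
#' @export
read_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fibril_id", "vertex_index", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    stop("read_traces: CSV must have columns ",
         paste(need, collapse = ", "))
  }
  ids <- unique(df$fibril_id)
  lapply(ids, function(id) {
    sub <- df[df$fibril_id == id, , drop = FALSE]
    sub <- sub[order(sub$vertex_index), ]
    fibril_trace(sub$x_nm, sub$y_nm, fibril_id = id)
  })
}

#' Read the first sequence from a FASTA file
#'
#' @param path FASTA path.
#' @return one-letter amino-acid string (gaps removed).
#' @export
read_sequence_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^>", lines[1])) {
    stop("read_sequence_fasta: not a FASTA file: ", path)
  }
  body <- lines[-1]
  nxt <- grep("^>", body)
  if (length(nxt) > 0) body <- body[seq_len(nxt[1] - 1)]
  gsub("[-. ]", "", paste(body, collapse = ""))
}

#' Write one sequence as FASTA
#'
#' @param sequence amino-acid string.
#' @param path output path.
#' @param name record header.
#' @export
write_sequence_fasta <- function(sequence, path, name = "seq") {
  chunks <- substring(sequence, seq(1, nchar(sequence), 60),
                      pmin(seq(1, nchar(sequence), 60) + 59,
                           nchar(sequence)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}
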