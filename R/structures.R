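# Coarse-grained bead structures: PDB/GRO input and output, backbone
# selection, optimal-superposition RMSD, trajectories and end-to-end
# distances. Internal length unit is nm everywhere; PDB files (angstrom)
# are converted on read and on write.

#' Construct a bead structure
#'
#' A `bead_structure` holds an ordered set of coarse-grained beads with
#' 1-based indices, bead and residue names, and 3-D coordinates in nm.
#'
#' @param beads data frame with columns `index`, `name`, `residue_index`,
#'   `residue_name`, `x`, `y`, `z` (coordinates in nm).
#' @param title short descriptive string.
#' @return An object of class `bead_structure`.
#' @export
bead_structure <- function(beads, title = "") {
  stopifnot(is.data.frame(beads))
  req <- c("index", "name", "residue_index", "residue_name", "x", "y", "z")
  missing_cols <- setdiff(req, names(beads))
  if (length(missing_cols) > 0) {
    stop("bead data frame lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(beads) == 0L) {
    abort_enmix("bead structure must contain at least one bead", "enmix_empty_input")
  }
  beads$index <- as.integer(beads$index)
  beads$residue_index <- as.integer(beads$residue_index)
  if (anyDuplicated(beads$index)) {
    stop("bead indices must be unique")
  }
  if (is.unsorted(beads$index, strictly = TRUE)) {
    stop("bead indices must be strictly increasing")
  }
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")])))) {
    stop("bead coordinates must be finite")
  }
  structure(list(beads = beads[, req], title = title), class = "bead_structure")
}

#' @export
print.bead_structure <- function(x, ...) {
  cat(sprintf(
    "<bead_structure> %d beads, %d residues%s\n",
    nrow(x$beads), length(unique(x$beads$residue_index)),
    if (nzchar(x$title)) paste0(", '", x$title, "'") else ""
  ))
  invisible(x)
}

#' @export
length.bead_structure <- function(x) nrow(x$beads)

#' Extract the coordinate matrix of a structure
#'
#' @param s a `bead_structure`, or a numeric matrix passed through unchanged.
#' @return Numeric matrix with one row per bead and columns x, y, z (nm).
#' @export
coords <- function(s) {
  if (is.matrix(s)) return(s)
  stopifnot(inherits(s, "bead_structure"))
  m <- as.matrix(s$beads[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  stop("cannot guess coordinate format from extension '", ext,
       "'; pass format = \"pdb\" or \"gro\"")
}

#' Read a coarse-grained coordinate file
#'
#' Reads PDB (ATOM records, first MODEL only, angstrom converted to nm) or
#' GRO (fixed-column, already nm) files into a [bead_structure()]. HETATM
#' records and altloc/occupancy fields are ignored.
#'
#' @param path file path.
#' @param format `"pdb"`, `"gro"`, or `"auto"` (guess from the extension).
#' @return A `bead_structure` with coordinates in nm.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") parse_pdb(lines, path) else parse_gro(lines, path)
}

num_field <- function(line, from, to, what, lineno) {
  txt <- trimws(substr(line, from, to))
  v <- suppressWarnings(as.numeric(txt))
  if (is.na(v)) {
    abort_enmix(
      sprintf("malformed %s field '%s' at line %d", what, txt, lineno),
      "enmix_parse_error"
    )
  }
  v
}

parse_pdb <- function(lines, path) {
  title <- ""
  recs <- list()
  serial <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    tag <- substr(line, 1, 6)
    if (startsWith(line, "TITLE")) {
      title <- trimws(paste(title, trimws(substr(line, 11, nchar(line)))))
    } else if (startsWith(line, "ENDMDL")) {
      break  # first model only
    } else if (tag == "ATOM  ") {
      serial <- serial + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        index = serial,
        name = trimws(substr(line, 13, 16)),
        residue_index = as.integer(num_field(line, 23, 26, "residue number", ln)),
        residue_name = trimws(substr(line, 18, 21)),
        x = num_field(line, 31, 38, "x coordinate", ln) / 10,
        y = num_field(line, 39, 46, "y coordinate", ln) / 10,
        z = num_field(line, 47, 54, "z coordinate", ln) / 10,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(recs) == 0L) {
    abort_enmix(
      paste0("no ATOM records (protein beads) found in ", path),
      "enmix_empty_input"
    )
  }
  bead_structure(do.call(rbind, recs), title = title)
}

parse_gro <- function(lines, path) {
  if (length(lines) < 2L) {
    abort_enmix(paste0("truncated GRO file: ", path), "enmix_parse_error")
  }
  title <- trimws(lines[[1L]])
  n <- suppressWarnings(as.integer(trimws(lines[[2L]])))
  if (is.na(n) || n < 1L) {
    abort_enmix(paste0("no beads declared in GRO file: ", path), "enmix_empty_input")
  }
  if (length(lines) < 2L + n) {
    abort_enmix(sprintf("GRO file declares %d beads but has %d atom lines",
                        n, length(lines) - 2L), "enmix_parse_error")
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- 2L + i
    line <- lines[[ln]]
    rows[[i]] <- data.frame(
      index = i,
      name = trimws(substr(line, 11, 15)),
      residue_index = as.integer(num_field(line, 1, 5, "residue number", ln)),
      residue_name = trimws(substr(line, 6, 10)),
      x = num_field(line, 21, 28, "x coordinate", ln),
      y = num_field(line, 29, 36, "y coordinate", ln),
      z = num_field(line, 37, 44, "z coordinate", ln),
      stringsAsFactors = FALSE
    )
  }
  bead_structure(do.call(rbind, rows), title = title)
}

#' Write a coarse-grained coordinate file
#'
#' Inverse of [read_structure()]: PDB output is in angstrom, GRO in nm.
#' GRO output appends a generous cubic box line (required by the format).
#'
#' @param s a `bead_structure`.
#' @param path output file path.
#' @param format `"pdb"`, `"gro"`, or `"auto"`.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "gro")) {
  stopifnot(inherits(s, "bead_structure"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  b <- s$beads
  if (format == "pdb") {
    lines <- c(
      if (nzchar(s$title)) sprintf("TITLE     %s", s$title) else character(0),
      sprintf(
        "ATOM  %5d %-4s %-4s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        b$index, substr(b$name, 1, 4), substr(b$residue_name, 1, 4),
        b$residue_index, b$x * 10, b$y * 10, b$z * 10
      ),
      "END"
    )
  } else {
    box <- max(1, ceiling(max(abs(as.matrix(b[, c("x", "y", "z")]))) * 2 + 2))
    lines <- c(
      if (nzchar(s$title)) s$title else "bead structure",
      sprintf("%5d", nrow(b)),
      sprintf(
        "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
        b$residue_index, substr(b$residue_name, 1, 5), substr(b$name, 1, 5),
        b$index %% 100000L, b$x, b$y, b$z
      ),
      sprintf("%10.5f%10.5f%10.5f", box, box, box)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Select backbone beads
#'
#' Keeps beads whose name is in `backbone_names` (default `"BB"`, the
#' Martini backbone bead). Side-chain beads are excluded from elastic
#' networks, which restrain the backbone only. The original bead indices
#' are retained in attribute `"orig_index"` so network terms can be mapped
#' back onto the full structure.
#'
#' @param s a `bead_structure`.
#' @param backbone_names character vector of bead names to keep.
#' @return A `bead_structure` of the selected beads, reindexed from 1, with
#'   attribute `orig_index`; a zero-selection yields a warning and `NULL`.
#' @export
select_backbone <- function(s, backbone_names = "BB") {
  stopifnot(inherits(s, "bead_structure"))
  keep <- s$beads$name %in% backbone_names
  if (!any(keep)) {
    warning("backbone selection is empty (no bead named ",
            paste(backbone_names, collapse = "/"), ")")
    return(NULL)
  }
  b <- s$beads[keep, , drop = FALSE]
  orig <- b$index
  b$index <- seq_len(nrow(b))
  out <- bead_structure(b, title = s$title)
  attr(out, "orig_index") <- orig
  out
}

kabsch_rotation <- function(p, q) {
  # optimal proper rotation R such that q %*% R best matches p (rows are
  # points, both centered); reflection excluded via the sign correction
  h <- crossprod(q, p)
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' With `fit = TRUE` the second set is first superposed onto the first by
#' the optimal rigid-body motion (translation plus proper rotation,
#' reflections excluded), the standard Kabsch solution.
#'
#' @param a,b coordinate matrices (rows = beads, columns = x,y,z in nm) or
#'   `bead_structure` objects.
#' @param fit apply optimal superposition before measuring (default `TRUE`).
#' @return RMSD in nm (non-negative scalar).
#' @export
rmsd <- function(a, b, fit = TRUE) {
  a <- coords(a); b <- coords(b)
  if (!all(dim(a) == dim(b))) {
    abort_enmix("coordinate sets differ in dimension", "enmix_dimension_error")
  }
  if (fit) {
    if (nrow(a) < 3L) stop("fitting requires at least 3 beads")
    ac <- colMeans(a); bc <- colMeans(b)
    a0 <- sweep(a, 2, ac); b0 <- sweep(b, 2, bc)
    b <- b0 %*% kabsch_rotation(a0, b0)
    a <- a0
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Construct a trajectory
#'
#' @param frames list of frames, each a list with elements `time` (ps) and
#'   `positions` (coordinate matrix in nm, same bead count as `reference`).
#' @param reference the `bead_structure` the frames refer to.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, reference) {
  stopifnot(inherits(reference, "bead_structure"), length(frames) > 0)
  nb <- nrow(reference$beads)
  times <- vapply(frames, function(f) as.numeric(f$time), numeric(1))
  if (is.unsorted(times)) stop("frame times must be nondecreasing")
  for (f in frames) {
    if (nrow(f$positions) != nb) {
      abort_enmix("frame bead count differs from reference", "enmix_dimension_error")
    }
  }
  structure(list(frames = frames, reference = reference), class = "trajectory")
}

#' Read a trajectory from a multi-model PDB or plain TSV
#'
#' The TSV layout is one row per frame: `time_ps` followed by
#' `x y z` triples for every bead in reference order.
#'
#' @param path file path.
#' @param reference `bead_structure` giving bead identity and count.
#' @param format `"pdb"` (MODEL/ENDMDL blocks) or `"tsv"`.
#' @param dt_ps frame spacing used to assign times to PDB models.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, reference, format = c("tsv", "pdb"), dt_ps = 50) {
  format <- match.arg(format)
  nb <- nrow(reference$beads)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = FALSE, comment.char = "#")
    if (ncol(tab) != 1 + 3 * nb) {
      abort_enmix(sprintf(
        "trajectory TSV has %d columns; expected %d (time + xyz per bead)",
        ncol(tab), 1 + 3 * nb), "enmix_dimension_error")
    }
    frames <- lapply(seq_len(nrow(tab)), function(r) {
      list(time = tab[r, 1],
           positions = matrix(as.numeric(tab[r, -1]), ncol = 3, byrow = TRUE))
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^MODEL", lines)
    ends <- grep("^ENDMDL", lines)
    if (length(starts) == 0L) stop("no MODEL records in ", path)
    frames <- mapply(function(s, e, i) {
      st <- parse_pdb(lines[(s + 1):(e - 1)], path)
      list(time = (i - 1) * dt_ps, positions = coords(st))
    }, starts, ends, seq_along(starts), SIMPLIFY = FALSE)
  }
  trajectory(frames, reference)
}

#' Per-frame end-to-end distance
#'
#' Euclidean distance between two chosen beads in every frame; by default
#' callers should use the first and last backbone bead, the conventional
#' measure of chain extension for an unfolded or disordered state.
#'
#' @param t a [trajectory()].
#' @param first_bead,last_bead 1-based bead indices into the reference.
#' @return Numeric vector of distances (nm), one per frame.
#' @export
end_to_end <- function(t, first_bead, last_bead) {
  stopifnot(inherits(t, "trajectory"))
  nb <- nrow(t$reference$beads)
  for (ix in c(first_bead, last_bead)) {
    if (ix < 1 || ix > nb) {
      abort_enmix(sprintf("bead index %d outside 1..%d", ix, nb),
                  "enmix_index_error")
    }
  }
  vapply(t$frames, function(f) {
    sqrt(sum((f$positions[first_bead, ] - f$positions[last_bead, ])^2))
  }, numeric(1))
}
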