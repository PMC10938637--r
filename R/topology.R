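# GROMACS-dialect topology subset: [moleculetype], [atoms], [bonds]
# (including the comment-marked "Rubber band" block), [constraints] and
# [angles] are modelled; everything else is preserved verbatim so that a
# round trip leaves the file intact. Supported bonded function types:
# bonds 1 and 6 (harmonic), angles 2 (cosine-harmonic) and 10 (restricted
# bending), constraints 1.

SUPPORTED_FUNCT <- list(bonds = c(1L, 6L), rubber_band = c(1L, 6L),
                        angles = c(2L, 10L), constraints = 1L)

#' Construct a topology object
#'
#' @param molecule_name molecule name from `[moleculetype]`.
#' @param atoms data frame: `index`, `type`, `residue_index`,
#'   `residue_name`, `bead_name`, `charge_group`, `charge`, `mass`
#'   (`mass` may be `NA`).
#' @param bonded data frame: `ai`, `aj`, `ak` (`NA` for two-body terms),
#'   `funct`, `c0`..`c3` (`c2`/`c3` are the optional B-state parameter set),
#'   `section_tag` in `bonds`, `rubber_band`, `angles`, `constraints`.
#' @param passthrough character vector of unrecognized lines (directive
#'   headers included) kept verbatim.
#' @param nrexcl exclusion number from `[moleculetype]`.
#' @return Object of class `topology`.
#' @export
topology <- function(molecule_name, atoms, bonded = empty_bonded(),
                     passthrough = character(0), nrexcl = 1L) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonded))
  atoms$index <- as.integer(atoms$index)
  if (nrow(atoms) == 0L) stop("topology needs at least one atom")
  if (!identical(atoms$index, seq_len(nrow(atoms)))) {
    stop("atom indices must be contiguous from 1")
  }
  if (nrow(bonded) > 0) {
    refs <- c(bonded$ai, bonded$aj, bonded$ak)
    refs <- refs[!is.na(refs)]
    bad <- refs < 1L | refs > nrow(atoms)
    if (any(bad)) {
      abort_enmix(
        sprintf("bonded term references atom %d but topology has %d atoms",
                refs[bad][1], nrow(atoms)),
        "enmix_validation_error"
      )
    }
    for (tag in unique(bonded$section_tag)) {
      ok <- SUPPORTED_FUNCT[[tag]]
      f <- bonded$funct[bonded$section_tag == tag]
      if (!is.null(ok) && !all(f %in% ok)) {
        abort_enmix(
          sprintf("unsupported funct %d in [%s] section",
                  setdiff(f, ok)[1], tag),
          "enmix_unsupported_funct"
        )
      }
    }
  }
  structure(
    list(molecule_name = molecule_name, nrexcl = as.integer(nrexcl),
         atoms = atoms, bonded = bonded, passthrough = passthrough),
    class = "topology"
  )
}

empty_bonded <- function() {
  data.frame(ai = integer(0), aj = integer(0), ak = integer(0),
             funct = integer(0), c0 = numeric(0), c1 = numeric(0),
             c2 = numeric(0), c3 = numeric(0),
             section_tag = character(0), stringsAsFactors = FALSE)
}

#' @export
print.topology <- function(x, ...) {
  counts <- table(x$bonded$section_tag)
  cat(sprintf("<topology> '%s': %d atoms; %s\n", x$molecule_name,
              nrow(x$atoms),
              if (length(counts)) paste(names(counts), as.integer(counts),
                                        sep = ":", collapse = ", ")
              else "no bonded terms"))
  invisible(x)
}

strip_comment <- function(line) sub(";.*$", "", line)

#' Parse a GROMACS-dialect topology file
#'
#' Captures `[moleculetype]`, `[atoms]`, `[bonds]` (lines following a
#' comment containing `rubber_marker` are tagged `rubber_band`),
#' `[constraints]` and `[angles]`. All other directives are kept verbatim
#' for round-trip writing. Bond lines may carry 2 or 4 parameters (a
#' second, B-state set).
#'
#' @param path file path (.itp/.top).
#' @param rubber_marker comment substring marking the elastic-network block
#'   inside `[bonds]` (default `"Rubber band"`).
#' @return A [topology()].
#' @export
parse_topology <- function(path, rubber_marker = "Rubber band") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  section <- ""
  in_rubber <- FALSE
  molecule_name <- "molecule"
  nrexcl <- 1L
  atoms <- list()
  bonded <- list()
  passthrough <- character(0)
  recognized <- c("moleculetype", "atoms", "bonds", "angles", "constraints")

  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    hdr <- regmatches(raw, regexec("^\\s*\\[\\s*([A-Za-z_]+)\\s*\\]", raw))[[1]]
    if (length(hdr) == 2) {
      section <- tolower(hdr[2])
      in_rubber <- FALSE
      if (!(section %in% recognized)) passthrough <- c(passthrough, raw)
      next
    }
    if (!(section %in% recognized)) {
      if (nzchar(trimws(raw)) && nzchar(section)) {
        passthrough <- c(passthrough, raw)
      }
      next
    }
    if (grepl("^\\s*;", raw)) {
      if (section == "bonds" && grepl(rubber_marker, raw, fixed = TRUE)) {
        in_rubber <- TRUE
      }
      next
    }
    body <- trimws(strip_comment(raw))
    if (!nzchar(body)) next
    tok <- strsplit(body, "\\s+")[[1]]
    if (section == "moleculetype") {
      molecule_name <- tok[1]
      if (length(tok) >= 2) nrexcl <- as.integer(tok[2])
    } else if (section == "atoms") {
      atoms[[length(atoms) + 1L]] <- data.frame(
        index = as.integer(tok[1]), type = tok[2],
        residue_index = as.integer(tok[3]), residue_name = tok[4],
        bead_name = tok[5],
        charge_group = if (length(tok) >= 6) as.integer(tok[6]) else NA_integer_,
        charge = if (length(tok) >= 7) as.numeric(tok[7]) else 0,
        mass = if (length(tok) >= 8) as.numeric(tok[8]) else NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      natm <- if (section == "angles") 3L else 2L
      if (length(tok) < natm + 1L) {
        abort_enmix(sprintf("short bonded record at line %d of %s", ln, path),
                    "enmix_parse_error")
      }
      prm <- suppressWarnings(as.numeric(tok[(natm + 2):length(tok)]))
      if (anyNA(prm) || !(length(prm) %in% c(1L, 2L, 4L))) {
        abort_enmix(sprintf("malformed parameters at line %d of %s", ln, path),
                    "enmix_parse_error")
      }
      tag <- if (section == "bonds" && in_rubber) "rubber_band" else section
      bonded[[length(bonded) + 1L]] <- data.frame(
        ai = as.integer(tok[1]), aj = as.integer(tok[2]),
        ak = if (natm == 3L) as.integer(tok[3]) else NA_integer_,
        funct = as.integer(tok[natm + 1L]),
        c0 = prm[1], c1 = if (length(prm) >= 2) prm[2] else NA_real_,
        c2 = if (length(prm) >= 3) prm[3] else NA_real_,
        c3 = if (length(prm) >= 4) prm[4] else NA_real_,
        section_tag = tag, stringsAsFactors = FALSE
      )
    }
  }
  if (length(atoms) == 0L) {
    abort_enmix(paste0("no [atoms] section in ", path), "enmix_parse_error")
  }
  topology(molecule_name, do.call(rbind, atoms),
           if (length(bonded)) do.call(rbind, bonded) else empty_bonded(),
           passthrough, nrexcl)
}

#' Convert restricted-bending angles to regular angles
#'
#' Rewrites every angle term with function type 10 (restricted bending,
#' which diverges near 180 degrees and cannot be lambda-perturbed by the
#' simulation engine) to type 2 (cosine-harmonic) with identical
#' parameters. Idempotent; all other terms are untouched.
#'
#' @param t a [topology()].
#' @return The converted topology.
#' @export
convert_restricted_angles <- function(t) {
  stopifnot(inherits(t, "topology"))
  sel <- t$bonded$section_tag == "angles" & t$bonded$funct == 10L
  t$bonded$funct[sel] <- 2L
  t
}

fmt_params <- function(row) {
  prm <- c(row$c0, row$c1, row$c2, row$c3)
  prm <- prm[!is.na(prm)]
  # odd slots are distances/angles (5 decimals), even slots force constants
  paste(vapply(seq_along(prm), function(i) {
    if (i %% 2 == 1) sprintf("%10.5f", prm[i]) else sprintf("%10.1f", prm[i])
  }, character(1)), collapse = " ")
}

bonded_lines <- function(b) {
  vapply(seq_len(nrow(b)), function(r) {
    row <- b[r, ]
    atoms <- if (is.na(row$ak)) sprintf("%5d %5d", row$ai, row$aj)
             else sprintf("%5d %5d %5d", row$ai, row$aj, row$ak)
    sprintf("%s %3d %s", atoms, row$funct, fmt_params(row))
  }, character(1))
}

#' Write a topology file
#'
#' Emits the recognized sections in canonical order, the rubber-band block
#' under its comment marker inside `[bonds]`, and the preserved
#' passthrough lines verbatim at the end. `parse_topology(write_topology(t))`
#' reproduces `t` field for field (reals at the emitted precision:
#' 5 decimals for distances/angles, 1 for force constants).
#'
#' @param t a [topology()].
#' @param path output path.
#' @param rubber_marker marker comment text for the elastic-network block.
#' @export
write_topology <- function(t, path, rubber_marker = "Rubber band") {
  stopifnot(inherits(t, "topology"))
  a <- t$atoms
  lines <- c(
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s %d", t$molecule_name, t$nrexcl),
    "",
    "[ atoms ]",
    sprintf("%5d %8s %5d %5s %5s %5d %8.4f%s",
            a$index, a$type, a$residue_index, a$residue_name, a$bead_name,
            ifelse(is.na(a$charge_group), a$index, a$charge_group), a$charge,
            ifelse(is.na(a$mass), "", sprintf(" %8.4f", a$mass)))
  )
  b <- t$bonded
  plain_bonds <- b[b$section_tag == "bonds", , drop = FALSE]
  rubber <- b[b$section_tag == "rubber_band", , drop = FALSE]
  if (nrow(plain_bonds) + nrow(rubber) > 0) {
    lines <- c(lines, "", "[ bonds ]")
    if (nrow(plain_bonds)) lines <- c(lines, bonded_lines(plain_bonds))
    if (nrow(rubber)) {
      lines <- c(lines, paste0("; ", rubber_marker), bonded_lines(rubber))
    }
  }
  for (sec in c("constraints", "angles")) {
    rows <- b[b$section_tag == sec, , drop = FALSE]
    if (nrow(rows)) {
      lines <- c(lines, "", sprintf("[ %s ]", sec), bonded_lines(rows))
    }
  }
  if (length(t$passthrough)) lines <- c(lines, "", t$passthrough)
  writeLines(lines, path)
  invisible(path)
}
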