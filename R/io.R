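#' Write a tube model or asymmetric unit to PDB or mmCIF
#'
#' PDB output goes through bio3d and is limited by the format's single
#' character chain field: tubes with more than 62 subunits either error or
#' recycle chain identifiers, per `chain_overflow`. mmCIF output (the
#' default for large models) labels each subunit by its lattice
#' coordinates in the `auth_asym_id` field and has no such limit.
#'
#' @param x A [build_tube()] model or an [asym_unit()].
#' @param path Output file; format inferred from the extension when
#'   `format` is `NULL` (`.pdb` or `.cif`).
#' @param format `"pdb"`, `"cif"`, or `NULL` to infer.
#' @param chain_overflow What to do when a PDB tube needs more than 62
#'   chains: `"error"` (default) or `"recycle"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(x, path, format = NULL,
                        chain_overflow = c("error", "recycle")) {
  chain_overflow <- match.arg(chain_overflow)
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "cif"
  }
  format <- match.arg(format, c("pdb", "cif"))
  atoms <- if (inherits(x, "tube_model")) tube_atoms(x) else x$atoms
  if (format == "cif") {
    write_cif_atoms(atoms, path)
  } else {
    chains <- unique(atoms$chain)
    pool <- c(LETTERS, letters, as.character(0:9))
    if (length(chains) > length(pool) && chain_overflow == "error") {
      abort(sprintf(
        "PDB chain identifiers overflow (%d subunits > 62); write mmCIF or set chain_overflow = 'recycle'.",
        length(chains)))
    }
    map <- pool[(seq_along(chains) - 1L) %% length(pool) + 1L]
    names(map) <- chains
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(atoms)),
      resno = as.integer(atoms$resid),
      resid = atoms$resname,
      chain = unname(map[atoms$chain]),
      elety = atoms$atom,
      o = atoms$occupancy,
      b = atoms$b_factor,
      elesy = atoms$element
    )
  }
  invisible(path)
}

write_cif_atoms <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_tubewrap_model",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_asym_id"
  ), con)
  writeLines(sprintf(
    "ATOM %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f %s",
    seq_len(nrow(atoms)), atoms$element, atoms$atom, atoms$resname,
    atoms$chain, as.integer(atoms$resid), atoms$x, atoms$y, atoms$z,
    atoms$occupancy, atoms$b_factor, atoms$chain
  ), con)
  writeLines("#", con)
  invisible(path)
}

## minimal mmCIF atom_site reader (loop_ table with whitespace-separated rows)
read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- which(trimws(lines) == "loop_")
  for (start in i) {
    j <- start + 1L
    fields <- character()
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1L
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
          ln == "loop_" || startsWith(ln, "data_")) break
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tok) != length(fields)) {
        abort(sprintf("mmCIF parse error at line %d: %d tokens for %d fields.",
                      j, length(tok), length(fields)))
      }
      rows[[length(rows) + 1L]] <- tok
      j <- j + 1L
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_atom_site\\.", "", fields)
    df <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
    get <- function(nm, default = NULL) if (nm %in% names(df)) df[[nm]] else default
    n <- nrow(df)
    element <- get("type_symbol")
    atom <- get("label_atom_id", rep("CA", n))
    if (is.null(element) || all(element %in% c("?", "."))) {
      warn("mmCIF file lacks element symbols; inferring from atom names.")
      element <- infer_element(atom)
    }
    return(tibble(
      element = element,
      atom = atom,
      resname = get("label_comp_id", rep("ALA", n)),
      chain = get("auth_asym_id", get("label_asym_id", rep("A", n))),
      resid = suppressWarnings(as.integer(get("label_seq_id", seq_len(n)))),
      x = as.numeric(get("Cartn_x")),
      y = as.numeric(get("Cartn_y")),
      z = as.numeric(get("Cartn_z")),
      occupancy = as.numeric(get("occupancy", rep(1, n))),
      b_factor = as.numeric(get("B_iso_or_equiv", rep(30, n)))
    ))
  }
  abort(sprintf("no _atom_site loop found in '%s'.", path))
}

infer_element <- function(atom_names) {
  e <- sub("^([0-9]*)([A-Za-z]).*$", "\\2", atom_names)
  toupper(e)
}

#' Read an asymmetric unit from PDB or mmCIF
#'
#' PDB files are parsed with bio3d; mmCIF files with the package's
#' `atom_site` reader. A missing element column is inferred from atom
#' names with a warning.
#'
#' @param path Model file (`.pdb` or `.cif`).
#' @param radial_reference Outward unit vector to attach, default `+x`.
#' @return An [asym_unit()].
#' @export
read_unit <- function(path, radial_reference = c(1, 0, 0)) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    pdb <- tryCatch(bio3d::read.pdb(path),
                    error = function(e) abort(sprintf(
                      "failed to parse PDB '%s': %s", path, conditionMessage(e))))
    a <- pdb$atom
    element <- a$elesy
    if (is.null(element) || all(is.na(element) | element == "")) {
      warn("PDB file lacks element symbols; inferring from atom names.")
      element <- infer_element(a$elety)
    }
    atoms <- tibble(
      element = element, atom = a$elety, resname = a$resid,
      chain = ifelse(is.na(a$chain), "A", a$chain),
      resid = a$resno, x = a$x, y = a$y, z = a$z,
      occupancy = ifelse(is.na(a$o), 1, a$o),
      b_factor = ifelse(is.na(a$b), 30, a$b)
    )
  } else {
    atoms <- read_cif_atoms(path)
  }
  asym_unit(atoms, radial_reference = radial_reference)
}
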