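# Multi-model PDB and sidecar topology I/O.
#
# PDB files cannot carry partial charges or atomic numbers, which the
# electron-density stage needs, so topologies travel in a delimited sidecar
# table and the PDB only carries coordinates and atom identity.

pdb_field <- function(lines, from, to) trimws(substring(lines, from, to))

#' Read a multi-model PDB file as a trajectory
#'
#' Frames are delimited by `MODEL`/`ENDMDL` records; a file without `MODEL`
#' records yields a single frame. Atom identity is parsed from `ATOM` and
#' `HETATM` records using the fixed PDB column convention. The element is
#' taken from columns 77-78 when present, otherwise inferred from the first
#' alphabetic character of the atom name. Occupancy and B-factor are ignored.
#' A `CRYST1` record, when present, provides the box dimensions.
#'
#' Partial charges are set to zero on read; supply them through
#' [read_topology_table()] if an electron-density profile needs them.
#'
#' @param path Path to a PDB file.
#' @return A [trajectory()].
#' @export
read_multi_model_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("Empty PDB file: ", path))

  rec <- substring(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort(paste0("No ATOM/HETATM records in ", path))

  model_starts <- which(trimws(rec) == "MODEL")
  box <- NULL
  cryst <- which(trimws(rec) == "CRYST1")
  if (length(cryst) > 0) {
    box <- as.numeric(c(substring(lines[cryst[1]], 7, 15),
                        substring(lines[cryst[1]], 16, 24),
                        substring(lines[cryst[1]], 25, 33)))
    if (anyNA(box) || any(box <= 0)) box <- NULL
  }

  # Assign each ATOM line to a model block
  if (length(model_starts) == 0) {
    model_of <- rep(1L, sum(is_atom))
    model_ids <- 1L
  } else {
    block <- findInterval(which(is_atom), model_starts)
    if (any(block == 0)) abort(paste0("ATOM records before the first MODEL in ", path))
    model_of <- block
    model_ids <- seq_along(model_starts)
  }

  atom_lines <- lines[is_atom]
  counts <- tabulate(model_of, nbins = max(model_ids))
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    abort(paste0("Inconsistent atom counts across models in ", path,
                 ": model ", bad, " has ", counts[bad],
                 " atoms, expected ", counts[1]))
  }

  first <- atom_lines[model_of == model_ids[1]]
  name <- pdb_field(first, 13, 16)
  res_name <- pdb_field(first, 18, 20)
  chain <- pdb_field(first, 22, 22)
  chain[chain == ""] <- "A"
  res_id <- suppressWarnings(as.integer(pdb_field(first, 23, 26)))
  if (anyNA(res_id)) abort(paste0("Unparseable residue number in ", path))
  element <- pdb_field(first, 77, 78)
  fallback <- toupper(substring(gsub("[^A-Za-z].*", "", gsub("^[0-9]+", "", name)), 1, 1))
  element <- ifelse(element == "" | is.na(element), fallback, toupper(element))
  props <- element_properties(element)

  topology <- tibble(
    index = seq_along(first) - 1L,
    name = name, res_name = res_name, res_id = res_id, chain = chain,
    element = element, z_number = props$z_number,
    partial_charge = 0, mass = props$mass
  )

  xyz <- cbind(
    as.numeric(substring(atom_lines, 31, 38)),
    as.numeric(substring(atom_lines, 39, 46)),
    as.numeric(substring(atom_lines, 47, 54))
  )
  if (anyNA(xyz)) abort(paste0("Unparseable coordinates in ", path))
  frames <- lapply(model_ids, function(m) {
    f <- xyz[model_of == m, , drop = FALSE]
    dimnames(f) <- NULL
    f
  })
  trajectory(topology, frames, box = box)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; occupancy and B-factor are written as
#' 1.00 and 0.00. Coordinates are printed with the format's standard 0.001 A
#' precision.
#'
#' @param x A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multi_model_pdb <- function(x, path) {
  stopifnot(inherits(x, "trajectory"))
  top <- x$topology
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(x$box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       x$box[1], x$box[2], x$box[3], 90, 90, 90), con)
  }
  name4 <- ifelse(nchar(top$name) < 4, sprintf(" %-3s", top$name),
                  substring(top$name, 1, 4))
  serial <- (top$index %% 99999L) + 1L
  for (f in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    co <- x$frames[[f]]
    writeLines(sprintf(
      "ATOM  %5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name4, " ", substring(top$res_name, 1, 3), top$chain,
      top$res_id, co[, 1], co[, 2], co[, 3], 1, 0, top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an atom topology from a delimited table
#'
#' The table must carry one row per atom, in coordinate order, with header
#' columns `index,name,res_name,res_id,chain,element,z_number,partial_charge,
#' mass`. Comma- and tab-delimited files are both accepted (the delimiter is
#' sniffed from the header line). `z_number` is the atomic number Z and
#' `partial_charge` is in elementary-charge units, as used by
#' [electron_density_profile()].
#'
#' @param path Path to a CSV/TSV file.
#' @return A topology tibble.
#' @export
read_topology_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(TOPOLOGY_COLUMNS, names(df))
  if (length(missing) > 0) {
    abort(paste0("Topology table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort(paste0("Empty topology table: ", path))
  numify <- function(col, integer = FALSE) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      abort(paste0("Non-numeric `", col, "` in topology table at row(s) ",
                   paste(which(is.na(v)), collapse = ", ")))
    }
    if (integer) as.integer(v) else v
  }
  out <- tibble(
    index = numify("index", integer = TRUE),
    name = df$name, res_name = df$res_name,
    res_id = numify("res_id", integer = TRUE),
    chain = df$chain, element = toupper(df$element),
    z_number = numify("z_number", integer = TRUE),
    partial_charge = numify("partial_charge"),
    mass = numify("mass")
  )
  validate_topology(out)
  out
}

#' Write a topology table
#' @param topology A topology tibble.
#' @param path Output path; tab-delimited if it ends in `.tsv`, else CSV.
#' @return `path`, invisibly.
#' @export
write_topology_table <- function(topology, path) {
  validate_topology(topology)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(topology, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
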