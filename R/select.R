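#' Select atoms with a small declarative expression language
#'
#' Selections are conjunctions of clauses joined by `&`. Five clause kinds are
#' supported, enough to address every atom group the analyses need (e.g.
#' phosphate groups, helix C-alpha atoms, a residue range):
#'
#' * `name=CA` or `name=CA,N,C,O` — atom-name membership
#' * `res_name=SDP,CHL` — residue/species-name membership
#' * `element=P` — element membership
#' * `chain=A` — chain membership
#' * `res_id in [817,827]` — inclusive residue-id range
#' * `res_id=821,824` — explicit residue-id list
#'
#' @param topology A topology tibble.
#' @param expr A selection string, e.g. `"name=CA & res_id in [817,827]"`.
#' @return A sorted, duplicate-free integer vector of atom row positions
#'   (1-based, matching coordinate-matrix rows). May be empty.
#' @examples
#' top <- build_ideal_helix(helix_spec())$topology
#' select_atoms(top, "name=CA & res_id in [817,827]")
#' @export
select_atoms <- function(topology, expr) {
  validate_topology(topology)
  if (!is.character(expr) || length(expr) != 1 || !nzchar(trimws(expr))) {
    abort("Selection expression must be a non-empty string")
  }
  clauses <- trimws(strsplit(expr, "&", fixed = TRUE)[[1]])
  keep <- rep(TRUE, nrow(topology))
  for (cl in clauses) {
    keep <- keep & match_clause(topology, cl)
  }
  sort(unique(which(keep)))
}

match_clause <- function(topology, clause) {
  if (!nzchar(clause)) abort("Empty clause in selection expression")
  m <- regmatches(clause, regexec(
    "^res_id[[:space:]]+in[[:space:]]*\\[[[:space:]]*(-?[0-9]+)[[:space:]]*,[[:space:]]*(-?[0-9]+)[[:space:]]*\\]$",
    clause))[[1]]
  if (length(m) == 3) {
    lo <- as.integer(m[2]); hi <- as.integer(m[3])
    if (lo > hi) abort(paste0("Malformed selection clause (empty range): `", clause, "`"))
    return(topology$res_id >= lo & topology$res_id <= hi)
  }
  m <- regmatches(clause, regexec(
    "^(name|res_name|element|chain|res_id)[[:space:]]*=[[:space:]]*([^=]+)$",
    clause))[[1]]
  if (length(m) != 3) {
    abort(paste0("Malformed selection clause: `", clause, "`"))
  }
  field <- m[2]
  values <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  values <- values[nzchar(values)]
  if (length(values) == 0) abort(paste0("Malformed selection clause: `", clause, "`"))
  if (field == "res_id") {
    ids <- suppressWarnings(as.integer(values))
    if (anyNA(ids)) abort(paste0("Malformed selection clause: `", clause, "`"))
    return(topology$res_id %in% ids)
  }
  col <- topology[[field]]
  if (field == "element") values <- toupper(values)
  col %in% values
}

# Resolve a selection given either an expression string or explicit positions.
resolve_selection <- function(topology, selection) {
  if (is.character(selection)) {
    select_atoms(topology, selection)
  } else {
    idx <- as.integer(selection)
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > nrow(topology))) {
      abort("Selection indices out of range")
    }
    sort(unique(idx))
  }
}

selection_label <- function(selection) {
  if (is.character(selection)) selection else paste0("indices[", length(selection), "]")
}
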