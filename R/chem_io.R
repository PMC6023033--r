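#' Parse a SMILES string into a compound record
#'
#' Converts a SMILES string into a heavy-atom molecular graph suitable for
#' Signature fragmentation.  Aromaticity is perceived on the parsed
#' structure, salts/solvents are stripped to the largest covalent fragment,
#' and hydrogens are kept implicit (never stored as graph atoms).
#' Stereochemistry is ignored: Signatures are constitution-only descriptors.
#'
#' @param smiles a single SMILES string.
#' @param id identifier for the compound (opaque string).
#' @return an object of class `sig_compound` with elements `id`, `smiles`
#'   (the input string), `structure` (a `sig_mol` molecular graph),
#'   `activity_class` (`"active"`, `"inactive"` or `"unknown"`) and
#'   `ic50_um` (numeric, `NA` when unknown).
#' @examples
#' \dontrun{
#' rec <- parse_smiles("c1ccccc1", "benzene")
#' nrow(rec$structure$atoms)  # 6
#' }
#' @export
parse_smiles <- function(smiles, id = "mol1") {
  assert_that(is.character(smiles) && length(smiles) == 1L && nzchar(trimws(smiles)),
              "smiles must be a non-empty string")
  molfile <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(trimws(smiles), " ", id)),
    error = function(e) "")
  if (!nzchar(trimws(molfile)))
    stop(sprintf("malformed SMILES for '%s': %s", id, smiles), call. = FALSE)
  mol <- molfile_to_graph(molfile, id = id)
  if (nrow(mol$atoms) == 0L)
    stop(sprintf("empty structure after standardization for '%s': %s", id, smiles),
         call. = FALSE)
  rec <- new_compound(id = id, smiles = smiles, structure = mol)
  rec$molfile <- molfile
  rec
}

new_compound <- function(id, smiles, structure,
                         activity_class = "unknown", ic50_um = NA_real_) {
  structure(list(id = as.character(id), smiles = smiles, structure = structure,
                 activity_class = activity_class, ic50_um = ic50_um),
            class = "sig_compound")
}

# Build a sig_mol from V2000 molfile text.  The general path goes through
# ChemmineR; single-atom molecules are read directly from the counts/atom
# lines because ChemmineR's SDF validator rejects bond-free records.
molfile_to_graph <- function(molfile, id = "mol1") {
  lines <- strsplit(molfile, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L) stop("truncated molfile for ", id, call. = FALSE)
  natoms <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(lines[4L], 4L, 6L)))
  if (is.na(natoms) || natoms == 0L)
    stop("empty structure for ", id, call. = FALSE)
  if (natoms == 1L) {
    fields <- strsplit(trimws(lines[5L]), "\\s+")[[1L]]
    atoms <- data.frame(element = fields[4L], aromatic = FALSE,
                        charge = sdf_charge_code(as.integer(fields[6L])),
                        stringsAsFactors = FALSE)
    return(new_mol(id, atoms, empty_bonds()))
  }
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(lines))
  sdf_to_graph(sdfset[[1L]], id = id)
}

empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = integer(0),
             aromatic = logical(0))
}

new_mol <- function(id, atoms, bonds) {
  structure(list(id = id, atoms = atoms, bonds = bonds), class = "sig_mol")
}

# old-style V2000 atom-block charge codes
sdf_charge_code <- function(code) {
  if (is.na(code)) return(0L)
  switch(as.character(code),
         "1" = 3L, "2" = 2L, "3" = 1L, "5" = -1L, "6" = -2L, "7" = -3L, 0L)
}

# ChemmineR SDF -> heavy-atom colored graph with perceived aromaticity,
# reduced to the largest covalent fragment.
sdf_to_graph <- function(sdf, id = "mol1") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L, dimnames = list(NULL, names(bb)))
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  charge_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charges <- vapply(as.integer(charge_col), sdf_charge_code, integer(1))

  nb <- if (NROW(bb) > 0L && !all(bb[, 1L] == 0)) NROW(bb) else 0L
  bonds <- if (nb > 0L) {
    data.frame(i = as.integer(bb[seq_len(nb), 1L]),
               j = as.integer(bb[seq_len(nb), 2L]),
               order = as.integer(bb[seq_len(nb), 3L]),
               aromatic = as.integer(bb[seq_len(nb), 3L]) == 4L)
  } else empty_bonds()

  arom_atom <- rep(FALSE, n)
  if (nb > 0L) {
    ri <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(ri) && length(ri$RINGS)) {
      for (k in seq_along(ri$RINGS)) {
        if (!isTRUE(ri$AROMATIC[[k]])) next
        idx <- as.integer(sub("^.*_", "", ri$RINGS[[k]]))
        arom_atom[idx] <- TRUE
        cyc <- cbind(idx, c(idx[-1L], idx[1L]))
        for (r in seq_len(nrow(cyc))) {
          hit <- (bonds$i == cyc[r, 1L] & bonds$j == cyc[r, 2L]) |
                 (bonds$i == cyc[r, 2L] & bonds$j == cyc[r, 1L])
          bonds$aromatic[hit] <- TRUE
        }
      }
    }
    arom_atom[unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))] <- TRUE
  }

  atoms <- data.frame(element = elements, aromatic = arom_atom, charge = charges,
                      stringsAsFactors = FALSE)
  mol <- new_mol(id, atoms, bonds)
  mol <- drop_hydrogens(mol)
  largest_fragment(mol)
}

drop_hydrogens <- function(mol) {
  keep <- mol$atoms$element != "H"
  subset_mol(mol, which(keep))
}

largest_fragment <- function(mol) {
  n <- nrow(mol$atoms)
  if (n <= 1L) return(mol)
  comp <- graph_components(n, as.matrix(mol$bonds[, c("i", "j")]))
  if (max(comp) == 1L) return(mol)
  sizes <- tabulate(comp)
  subset_mol(mol, which(comp == which.max(sizes)))
}

# Restrict a molecule to the given atom indices, remapping bond endpoints.
subset_mol <- function(mol, keep) {
  map <- integer(nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  rownames(b) <- NULL
  new_mol(mol$id, mol$atoms[keep, , drop = FALSE], b)
}

#' @export
print.sig_mol <- function(x, ...) {
  cat(sprintf("<sig_mol %s: %d heavy atoms, %d bonds, %d aromatic>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), sum(x$bonds$aromatic)))
  invisible(x)
}

#' @export
print.sig_compound <- function(x, ...) {
  cat(sprintf("<sig_compound %s [%s]%s> %s\n", x$id, x$activity_class,
              if (!is.na(x$ic50_um)) sprintf(" IC50=%.3g uM", x$ic50_um) else "",
              x$smiles))
  invisible(x)
}

#' Construct a compound library
#'
#' @param records list of `sig_compound` records; ids must be unique.
#' @param provenance free-text origin tag carried through filters.
#' @return an object of class `sig_library`.
#' @export
sig_library <- function(records, provenance = "unspecified") {
  ids <- vapply(records, function(r) r$id, character(1))
  assert_that(!anyDuplicated(ids), "compound ids must be unique within a library")
  names(records) <- ids
  structure(list(records = records, provenance = provenance),
            class = "sig_library")
}

#' @export
length.sig_library <- function(x) length(x$records)

#' @export
`[.sig_library` <- function(x, i) sig_library(x$records[i], x$provenance)

#' @export
print.sig_library <- function(x, ...) {
  cls <- library_classes(x)
  cat(sprintf("<sig_library: %d compounds (%d active, %d inactive, %d unknown); provenance: %s>\n",
              length(x), sum(cls == "active"), sum(cls == "inactive"),
              sum(cls == "unknown"), x$provenance))
  invisible(x)
}

#' Library column accessors
#'
#' @param lib a `sig_library`.
#' @return character (ids, classes) or numeric (IC50 in uM) vector over the
#'   records, in library order.
#' @export
library_ids <- function(lib) vapply(lib$records, function(r) r$id, character(1), USE.NAMES = FALSE)

#' @rdname library_ids
#' @export
library_classes <- function(lib) vapply(lib$records, function(r) r$activity_class, character(1), USE.NAMES = FALSE)

#' @rdname library_ids
#' @export
library_ic50 <- function(lib) vapply(lib$records, function(r) r$ic50_um %||% NA_real_, numeric(1), USE.NAMES = FALSE)

#' @export
as.data.frame.sig_library <- function(x, ...) {
  data.frame(id = library_ids(x),
             smiles = vapply(x$records, function(r) r$smiles %||% NA_character_, character(1), USE.NAMES = FALSE),
             activity_class = library_classes(x),
             ic50_um = library_ic50(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

map_activity_class <- function(cls) {
  cls <- tolower(trimws(as.character(cls)))
  out <- rep("unknown", length(cls))
  out[cls %in% c("1", "active", "true", "a")] <- "active"
  out[cls %in% c("0", "inactive", "false", "i")] <- "inactive"
  out
}

#' Read a compound library from disk
#'
#' Supported formats: `smi` (one `SMILES<whitespace>id` per line), `sdf`
#' (V2000) and `csv` (columns `id`, `smiles`, optional `class`, optional
#' `ic50_um`; class is coded 1/0 or active/inactive).  Records that fail to
#' parse are counted and reported via a warning and the `n_skipped`
#' attribute, never silently dropped.  A present `ic50_um` implies the
#' active class; a record declared inactive with an IC50 is an error.
#'
#' @param path input file.
#' @param format one of `"smi"`, `"sdf"`, `"csv"`; default guesses from the
#'   file extension.
#' @return a `sig_library` with attribute `n_skipped`.
#' @export
read_library <- function(path, format = c("auto", "smi", "sdf", "csv")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste("no such file:", path))
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("smi", "sdf", "csv"))
      stop("cannot guess format from extension: ", path, call. = FALSE)
  }
  switch(format,
         smi = read_library_smi(path),
         csv = read_library_csv(path),
         sdf = read_library_sdf(path))
}

read_library_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list(); skipped <- 0L
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    cid <- if (length(tok) >= 2L) tok[2L] else sprintf("mol%05d", k)
    rec <- tryCatch(parse_smiles(tok[1L], cid), error = function(e) NULL)
    if (is.null(rec)) skipped <- skipped + 1L else recs[[length(recs) + 1L]] <- rec
  }
  finish_library(recs, skipped, provenance = path)
}

read_library_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("id", "smiles") %in% names(df)),
              "csv library needs columns 'id' and 'smiles'")
  cls <- if ("class" %in% names(df)) map_activity_class(df$class) else rep("unknown", nrow(df))
  ic50 <- if ("ic50_um" %in% names(df)) suppressWarnings(as.numeric(df$ic50_um)) else rep(NA_real_, nrow(df))
  bad <- !is.na(ic50) & cls == "inactive"
  assert_that(!any(bad), paste("records with an IC50 declared inactive:",
                               paste(df$id[bad], collapse = ", ")))
  cls[!is.na(ic50)] <- "active"
  recs <- list(); skipped <- 0L
  for (k in seq_len(nrow(df))) {
    rec <- tryCatch(parse_smiles(df$smiles[k], as.character(df$id[k])),
                    error = function(e) NULL)
    if (is.null(rec)) { skipped <- skipped + 1L; next }
    rec$activity_class <- cls[k]
    rec$ic50_um <- ic50[k]
    recs[[length(recs) + 1L]] <- rec
  }
  finish_library(recs, skipped, provenance = path)
}

read_library_sdf <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- suppressWarnings(ChemmineR::validSDF(sdfset))
  skipped <- sum(!valid)
  sdfset <- sdfset[valid]
  recs <- list()
  for (k in seq_along(sdfset)) {
    hdr <- as(sdfset[[k]], "SDF")@header
    cid <- trimws(hdr[["Molecule_Name"]] %||% hdr[[1L]])
    if (!nzchar(cid)) cid <- sprintf("mol%05d", k)
    rec <- tryCatch({
      mol <- sdf_to_graph(sdfset[[k]], id = cid)
      r <- new_compound(cid, smiles = NA_character_, structure = mol)
      r$molfile <- paste(ChemmineR::sdf2str(as(sdfset[[k]], "SDF")), collapse = "\n")
      r
    }, error = function(e) NULL)
    if (is.null(rec)) skipped <- skipped + 1L else recs[[length(recs) + 1L]] <- rec
  }
  finish_library(recs, skipped, provenance = path)
}

finish_library <- function(recs, skipped, provenance) {
  if (length(recs) == 0L) stop("zero parseable records in ", provenance, call. = FALSE)
  ids <- vapply(recs, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    for (k in dup) recs[[k]]$id <- paste0(ids[k], "_dup", k)
  }
  if (skipped > 0L)
    warning(sprintf("%d unparseable record(s) skipped in %s", skipped, provenance),
            call. = FALSE)
  lib <- sig_library(recs, provenance = provenance)
  attr(lib, "n_skipped") <- skipped
  lib
}

#' Write a compound library to disk
#'
#' @param lib a `sig_library` whose records carry SMILES strings.
#' @param path output file.
#' @param format `"smi"` or `"csv"`.
#' @export
write_library <- function(lib, path, format = c("smi", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(lib)
  assert_that(!anyNA(df$smiles), "library records lack SMILES; cannot write")
  if (format == "smi") {
    writeLines(paste(df$smiles, df$id), path)
  } else {
    df$class <- ifelse(df$activity_class == "active", 1L,
                       ifelse(df$activity_class == "inactive", 0L, NA_integer_))
    utils::write.csv(df[, c("id", "smiles", "class", "ic50_um")], path,
                     row.names = FALSE, na = "")
  }
  invisible(path)
}
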