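#' Atomic and molecular Signature descriptors
#'
#' An atomic Signature is a canonical string encoding the bonded
#' neighborhood of one root atom of a molecular graph out to a fixed graph
#' distance (the height), expanded without backtracking along the edge just
#' traversed.  The multiset of atomic Signatures over all heavy atoms and
#' all requested heights is the molecular Signature; the occurrence counts
#' over a library form the descriptor matrix fed to PCA/GA/SVM modelling.
#'
#' String dialect: each atom renders as `[X]` with aromatic atoms
#' lower-cased and formal charge appended (`[n+]`, `[O-]`); each child
#' subtree is prefixed with its bond symbol (`''` single, `=` double,
#' `#` triple, `:` aromatic) and children at every branch point are sorted
#' by lexicographic comparison of their fully rendered strings, which makes
#' the string invariant under atom relabeling.
#'
#' @param mol a `sig_mol` molecular graph (or a `sig_compound`).
#' @param root atom index (1-based) of the root atom.
#' @param height non-negative integer graph distance to expand to.
#' @return `atomic_signature()`: an object of class `sig_atomic` — a list
#'   with `height` and `canon` (the canonical string).
#' @seealso [molecular_signature()], [build_matrix()]
#' @export
atomic_signature <- function(mol, root, height) {
  mol <- as_sig_mol(mol)
  n <- nrow(mol$atoms)
  assert_that(is.numeric(root) && length(root) == 1L && root >= 1L && root <= n,
              sprintf("invalid root index %s (molecule has %d atoms)", toString(root), n))
  assert_that(is.numeric(height) && length(height) == 1L && height >= 0L,
              "height must be a non-negative integer")
  adj <- mol_adjacency(mol)
  canon <- sig_render(mol, adj, as.integer(root), 0L, as.integer(height))
  structure(list(height = as.integer(height), canon = canon), class = "sig_atomic")
}

#' @export
print.sig_atomic <- function(x, ...) {
  cat(sprintf("h%d %s\n", x$height, x$canon)); invisible(x)
}

as_sig_mol <- function(x) {
  if (inherits(x, "sig_compound")) x$structure
  else if (inherits(x, "sig_mol")) x
  else stop("expected a sig_mol or sig_compound", call. = FALSE)
}

# adjacency as a list of data.frames (neighbor atom, bond symbol, bond id)
mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- rep(list(list(nbr = integer(0), sym = character(0), bid = integer(0))), n)
  b <- mol$bonds
  if (nrow(b) == 0L) return(adj)
  sym <- ifelse(b$aromatic, ":", c("", "=", "#")[pmin(b$order, 3L)])
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j)
    adj[[i]]$sym <- c(adj[[i]]$sym, sym[k])
    adj[[i]]$bid <- c(adj[[i]]$bid, k)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i)
    adj[[j]]$sym <- c(adj[[j]]$sym, sym[k])
    adj[[j]]$bid <- c(adj[[j]]$bid, k)
  }
  adj
}

sig_atom_str <- function(mol, a) {
  el <- mol$atoms$element[a]
  if (mol$atoms$aromatic[a]) el <- tolower(el)
  q <- mol$atoms$charge[a]
  qs <- if (q > 0L) paste0("+", if (q > 1L) q else "") else
        if (q < 0L) paste0("-", if (q < -1L) -q else "") else ""
  paste0("[", el, qs, "]")
}

# Recursive no-backtracking expansion: from `atom`, reached via bond id
# `from_bid` (0 for the root), expand `h` more levels.  Children are sorted
# lexicographically on their full rendered (bond-prefixed) strings.  When a
# neighborhood is exhausted early the string degenerates to its lower-height
# form by construction.
sig_render <- function(mol, adj, atom, from_bid, h) {
  head <- sig_atom_str(mol, atom)
  if (h == 0L) return(head)
  nb <- adj[[atom]]
  keep <- nb$bid != from_bid
  if (!any(keep)) return(head)
  kids <- character(sum(keep))
  idx <- which(keep)
  for (t in seq_along(idx)) {
    k <- idx[t]
    kids[t] <- paste0(nb$sym[k],
                      sig_render(mol, adj, nb$nbr[k], nb$bid[k], h - 1L))
  }
  # C collation so canonical order is locale-independent
  kids <- kids[order(kids, method = "radix")]
  paste0(head, "(", paste0(kids, collapse = ""), ")")
}

#' Molecular Signature: atomic Signatures over all roots and heights
#'
#' @param heights integer vector of heights (default `0:2`).
#' @return an object of class `sig_molsig`: a named integer vector of
#'   occurrence counts keyed `"<height>:<canon>"`, with attributes
#'   `id`, `heights`, and a `keys` data.frame (height, canon).
#' @rdname atomic_signature
#' @export
molecular_signature <- function(mol, heights = 0:2) {
  cmp_id <- if (inherits(mol, "sig_compound")) mol$id else NULL
  mol <- as_sig_mol(mol)
  assert_that(length(heights) > 0L, "heights must be non-empty")
  heights <- sort(unique(as.integer(heights)))
  adj <- mol_adjacency(mol)
  n <- nrow(mol$atoms)
  keys <- character(0)
  for (h in heights) {
    canon <- vapply(seq_len(n), function(a) sig_render(mol, adj, a, 0L, h), character(1))
    keys <- c(keys, paste0(h, ":", canon))
  }
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(counts, id = cmp_id %||% mol$id, heights = heights, class = "sig_molsig")
}

sig_key_height <- function(keys) as.integer(sub(":.*$", "", keys))
sig_key_canon <- function(keys) sub("^[0-9]+:", "", keys)

#' @export
print.sig_molsig <- function(x, ...) {
  cat(sprintf("<molecular signature of %s: %d unique atomic signatures, heights {%s}>\n",
              attr(x, "id"), length(x), paste(attr(x, "heights"), collapse = ",")))
  invisible(x)
}

#' Build the compounds-by-signatures descriptor matrix
#'
#' Columns are the union of unique atomic Signatures over the library,
#' ordered deterministically by (height, canonical string); values are
#' occurrence counts.  Per-column minimum and maximum occurrence over the
#' compounds that contain the signature (the applicability-domain windows
#' used by [overlap()]) are recorded as `col_min`/`col_max`.
#'
#' When an atom's neighborhood is exhausted before the requested height the
#' rendered string equals its lower-height form but is still recorded under
#' the requested height; set `dedupe_degenerate_heights = TRUE` to merge
#' such degenerate duplicates into a single column keyed by the canonical
#' string alone (tagged with the smallest height producing it).
#'
#' @param lib a `sig_library` (or list of `sig_compound`/`sig_mol`).
#' @param heights integer vector of Signature heights.
#' @param dedupe_degenerate_heights merge columns whose canonical strings
#'   coincide across heights (default `FALSE`).
#' @return an object of class `sig_matrix`: list with `counts` (integer
#'   matrix, compounds x signatures), `height`, `canon`, `col_min`,
#'   `col_max`, `heights`, `dedupe`.
#' @export
build_matrix <- function(lib, heights = 0:2, dedupe_degenerate_heights = FALSE) {
  recs <- if (inherits(lib, "sig_library")) lib$records else lib
  assert_that(length(recs) > 0L, "library is empty")
  sigs <- lapply(recs, molecular_signature, heights = heights)
  ids <- vapply(seq_along(sigs), function(k) attr(sigs[[k]], "id") %||% paste0("mol", k),
                character(1))
  if (dedupe_degenerate_heights) {
    sigs <- lapply(sigs, function(s) {
      canon <- sig_key_canon(names(s))
      h <- sig_key_height(names(s))
      # merge per molecule: keep smallest height tag per canonical string
      agg <- tapply(as.integer(s), canon, sum)
      minh <- tapply(h, canon, min)
      out <- as.integer(agg)
      names(out) <- paste0(minh[names(agg)], ":", names(agg))
      out
    })
  }
  all_keys <- sort(unique(unlist(lapply(sigs, names))), method = "radix")
  h <- sig_key_height(all_keys)
  ord <- order(h, sig_key_canon(all_keys), method = "radix")
  all_keys <- all_keys[ord]
  counts <- matrix(0L, nrow = length(sigs), ncol = length(all_keys),
                   dimnames = list(ids, all_keys))
  for (k in seq_along(sigs)) counts[k, names(sigs[[k]])] <- as.integer(sigs[[k]])
  col_min <- apply(counts, 2L, function(v) min(v[v > 0L]))
  col_max <- apply(counts, 2L, max)
  structure(list(counts = counts,
                 height = sig_key_height(all_keys),
                 canon = sig_key_canon(all_keys),
                 col_min = col_min, col_max = col_max,
                 heights = sort(unique(as.integer(heights))),
                 dedupe = dedupe_degenerate_heights),
            class = "sig_matrix")
}

#' @export
print.sig_matrix <- function(x, ...) {
  tallies <- table(factor(x$height, levels = sort(unique(x$height))))
  cat(sprintf("<sig_matrix: %d compounds x %d unique atomic signatures (%s)>\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s h=%s", tallies, names(tallies)), collapse = "; ")))
  invisible(x)
}

#' @export
dim.sig_matrix <- function(x) dim(x$counts)

# Project a molecular signature onto a fixed vocabulary (matrix columns),
# dropping out-of-vocabulary signatures (those affect only the overlap).
project_counts <- function(molsig, keys) {
  v <- numeric(length(keys))
  names(v) <- keys
  hit <- intersect(names(molsig), keys)
  v[hit] <- as.numeric(molsig[hit])
  v
}

#' Serialize a descriptor matrix
#'
#' Writes the count matrix as CSV (rows = compounds) and a JSON sidecar
#' holding the column signatures with their occurrence windows.
#'
#' @param dm a `sig_matrix`.
#' @param csv_path,json_path output paths.
#' @export
write_matrix <- function(dm, csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(as.data.frame(dm$counts), csv_path)
  jsonlite::write_json(list(keys = colnames(dm$counts), height = dm$height,
                            canon = dm$canon, col_min = dm$col_min,
                            col_max = dm$col_max, heights = dm$heights,
                            dedupe = dm$dedupe),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
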