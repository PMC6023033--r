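# Independent brute-force signature oracle.
#
# Builds the no-backtracking expansion tree explicitly as nested lists and
# renders it bottom-up, sorting children at each node.  Shares no code with
# the package's renderer beyond the dialect definition (bracketed atoms,
# lower-case aromatics, bond-symbol prefixes, lexicographic child order).

oracle_atom_label <- function(mol, a) {
  el <- mol$atoms$element[a]
  if (mol$atoms$aromatic[a]) el <- tolower(el)
  ch <- mol$atoms$charge[a]
  suffix <- ""
  if (ch > 0) suffix <- if (ch == 1) "+" else paste0("+", ch)
  if (ch < 0) suffix <- if (ch == -1) "-" else paste0("-", abs(ch))
  paste0("[", el, suffix, "]")
}

oracle_bond_table <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(b)
  b$sym <- ifelse(b$aromatic, ":", ifelse(b$order == 2, "=", ifelse(b$order == 3, "#", "")))
  b
}

# explicit tree: list(atom, bond_sym, children = list(...))
oracle_build_tree <- function(mol, bt, atom, via_bond, h) {
  node <- list(atom = atom)
  if (h == 0L || nrow(bt) == 0L) return(node)
  inc <- which((bt$i == atom | bt$j == atom) & seq_len(nrow(bt)) != via_bond)
  kids <- list()
  for (k in inc) {
    other <- if (bt$i[k] == atom) bt$j[k] else bt$i[k]
    child <- oracle_build_tree(mol, bt, other, k, h - 1L)
    child$bond_sym <- bt$sym[k]
    kids[[length(kids) + 1L]] <- child
  }
  if (length(kids)) node$children <- kids
  node
}

oracle_render_tree <- function(mol, node) {
  lab <- oracle_atom_label(mol, node$atom)
  if (is.null(node$children)) return(lab)
  rendered <- vapply(node$children, function(ch)
    paste0(ch$bond_sym, oracle_render_tree(mol, ch)), character(1))
  rendered <- sort(rendered, method = "radix")
  paste0(lab, "(", paste(rendered, collapse = ""), ")")
}

oracle_atomic_signature <- function(mol, root, h) {
  if (inherits(mol, "sig_compound")) mol <- mol$structure
  bt <- oracle_bond_table(mol)
  tree <- oracle_build_tree(mol, bt, root, 0L, h)
  oracle_render_tree(mol, tree)
}

oracle_molecular_signature <- function(mol, heights = 0:2) {
  if (inherits(mol, "sig_compound")) mol <- mol$structure
  keys <- character(0)
  for (h in sort(heights)) {
    for (a in seq_len(nrow(mol$atoms)))
      keys <- c(keys, paste0(h, ":", oracle_atomic_signature(mol, a, h)))
  }
  sort(keys, method = "radix")
}

# Random relabeling of a molecule's atom indices (bond rows shuffled too).
permute_mol <- function(mol, perm) {
  if (inherits(mol, "sig_compound")) mol <- mol$structure
  n <- nrow(mol$atoms)
  stopifnot(length(perm) == n)
  atoms <- mol$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  b$i <- perm[b$i]
  b$j <- perm[b$j]
  if (nrow(b) > 1L) b <- b[sample.int(nrow(b)), , drop = FALSE]
  rownames(b) <- NULL
  structure(list(id = mol$id, atoms = atoms, bonds = b), class = "sig_mol")
}

# sorted multiset of signature keys for comparisons
sig_multiset <- function(molsig) {
  sort(rep(names(molsig), as.integer(molsig)), method = "radix")
}

# A labelled library with an exact number of actives (IC50s drawn
# deterministically), used for augmentation arithmetic.
make_labelled_lib <- function(n, n_active, seed = 1) {
  lib <- generate_library(planted_rule(), n = n, active_fraction = 0, seed = seed)
  recs <- lib$records
  for (k in seq_len(n)) {
    recs[[k]]$activity_class <- if (k <= n_active) "active" else "inactive"
    recs[[k]]$ic50_um <- if (k <= n_active) 1 + k else NA_real_
  }
  sig_library(recs, provenance = sprintf("synthetic labelled library (%d/%d)", n_active, n))
}

fixture_smiles <- c(
  ethanol = "CCO",
  isobutane = "CC(C)C",
  benzene = "c1ccccc1",
  pyridine = "c1ccncc1",
  acetic_acid = "CC(=O)O",
  cyclopropane = "C1CC1",
  acrylonitrile = "C=CC#N",
  serinol_frag = "OCC(N)=O",
  thf = "C1CCOC1",
  chlorobenzene = "Clc1ccccc1",
  nitroethane = "CC[N+](=O)[O-]")

small_ga <- function() ga_config(population = 20, max_iter = 12, stall_stop = 5)
small_spec <- function(task = "classification")
  svm_spec(task, cost_grid = c(0.01, 0.1, 1), folds = 10)

# One fitted ensemble shared across test files (fitting dominates runtime).
shared_fit <- local({
  env <- new.env()
  function() {
    if (is.null(env$ens)) {
      env$train <- generate_library(planted_rule(), n = 200,
                                    active_fraction = 0.118, seed = 7)
      env$ens <- sigscreen_fit(env$train, spec = small_spec(), ga = small_ga(),
                               seed = 3)
    }
    list(train = env$train, ens = env$ens)
  }
})
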