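# Shared fixtures, all built in code at test time.

# Write a small FASTA/PHYLIP/newick string to a temp file and return its path.
tmpfile_with <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Balanced ultrametric 4-taxon tree: the central edge is the clock root.
ultrametric4 <- function() parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")

# An msa from explicit sequences.
msa_from <- function(labels, seqs) {
  read_fasta(tmpfile_with(paste0(">", labels, "\n", seqs), ".fasta"))
}

# A reversible model whose root frequencies equal the stationary
# distribution: likelihood is then invariant to root placement.
pulley_params <- function(n_cats = 1L, p_inv = 0) {
  reversible_params(freqs = c(0.15, 0.35, 0.30, 0.20),
                    exch = c(1, 2.5, 0.8, 1.3, 3.1, 0.6),
                    n_cats = n_cats, p_inv = p_inv)
}

# Simulated non-reversible fixture: tree, model, alignment.
sim_fixture <- function(n_taxa, n_sites, seed, n_cats = 1L, p_inv = 0) {
  rooted <- random_rooted_tree(n_taxa, seed = seed)
  model <- random_model(seed = seed + 1000L, n_cats = n_cats, p_inv = p_inv)
  msa <- simulate_msa(rooted, model, n_sites, seed = seed + 2000L)
  list(rooted = rooted, tree = rooted$tree, model = model, msa = msa)
}
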