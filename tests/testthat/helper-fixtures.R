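# Shared fixtures, memoized so expensive folding work runs once per suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small planted genome covering every hairpin label
shared_reference <- function() {
  memo("shared_reference", function() {
    make_reference(11, n_pass = 3L, n_fail = 5L)
  })
}

# one small end-to-end synthetic run through the full pipeline
shared_e2e <- function() {
  memo("shared_e2e", function() {
    out_dir <- file.path(tempdir(), "coldsmRNA_e2e")
    sim <- simulate_run(7, file.path(out_dir, "sim"), depth = 20000,
                        format = "fastq", n_pass = 3L, n_fail = 2L)
    res <- run_pipeline(
      inputs = list(fastq = sim$libraries$fastq,
                    adapter3 = sim$libraries$adapter3,
                    adapter5 = sim$libraries$adapter5,
                    genome = sim$paths$genome, known = sim$known,
                    ncrna = sim$ncrna, go_map = sim$go$annotation,
                    kegg_map = sim$kegg$annotation),
      out_dir = file.path(out_dir, "run"))
    list(sim = sim, res = res, out_dir = out_dir)
  })
}

# engine wrapper that keeps RNAfold structures but overrides the MFE,
# for threshold tests that must not depend on engine energies
fixed_mfe_engine <- function(mfe) {
  real <- rnafold_engine()
  function(seqs) {
    r <- real(seqs)
    r$mfe <- rep(mfe, nrow(r))
    r
  }
}

# a known-miRNA reference with one precursor and fully controlled coordinates
tiny_known_ref <- function() {
  set.seed(404)
  prec <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  mirna_reference("mir_test", prec, 30L, 50L)
}
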