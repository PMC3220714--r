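# small hand-built fixtures shared across test files

mini_design <- function(n_primary = 5, n_secondary = 5) {
  rd_design(n_primary, n_secondary,
            patches = data.frame(patch_id = c("A", "B"),
                                 landscape = c(50, 30)))
}

# one individual with captures at given (session, occasion) pairs
make_ind <- function(id, patch, at, design, age = "adult") {
  enc <- matrix(0L, design$n_primary, design$n_secondary)
  agem <- matrix(NA_character_, design$n_primary, design$n_secondary)
  if (length(age) == 1) age <- rep(age, nrow(at))
  for (i in seq_len(nrow(at))) {
    enc[at[i, 1], at[i, 2]] <- 1L
    agem[at[i, 1], at[i, 2]] <- age[i]
  }
  list(id = id, patch_id = patch, enc = enc, age = agem)
}

# all 2^n - 1 nonzero binary vectors of length n, as a matrix
nonzero_histories <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

# single-patch truth helper for recovery experiments
uniform_truth <- function(n_patches = 6, N1 = 40, phi = 0.6,
                          imm_rate = 16, young_rate = 0,
                          p = 0.4, c = 0.4, T_ = 5, K = 5) {
  des <- rd_design(T_, K,
                   patches = data.frame(
                     patch_id = paste0("P", seq_len(n_patches)),
                     landscape = rep(c(50, 30),
                                     length.out = n_patches)))
  rd_truth(des,
           patches = data.frame(patch_id = des$patches$patch_id,
                                N1 = N1, phi = phi, imm_rate = imm_rate,
                                young_rate = young_rate),
           p = p, c = c)
}
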