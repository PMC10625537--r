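# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Brute-force two-sided Mann-Whitney p-value by enumerating all C(n1+n2, n1)
# assignments of the pooled ranks to group 1.
mw_exact_bruteforce <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  # two-sided: arrangements at least as extreme (|U - mu|) as observed
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Nernst potential recomputed from first principles (independent constants
# source: CODATA values typed in directly)
nernst_oracle <- function(cl_i, cl_o, temp_k) {
  (8.314462618 * temp_k / 96485.33212) * log(cl_i / cl_o) * 1000
}

# quick field + full imaging pipeline round trip
quantify_synthetic_field <- function(..., seed) {
  fld <- sim_imaging_field(..., seed = seed)
  rois <- detect_somata(fld)
  ratios <- extract_cell_ratios(fld, rois)
  list(field = fld, rois = rois,
       cells = quantify_field(ratios, fld$calib, rois))
}
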