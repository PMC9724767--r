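# Shared fixture builders; everything is generated in code, seeded.

random_beta <- function(n_probes, n_samples, seed = 1, missing = 0) {
  set.seed(seed)
  m <- matrix(stats::runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  m
}

small_sheet <- function(ids, group = "control", age = 40, sex = "F") {
  data.frame(sample_id = ids,
             group = rep_len(group, length(ids)),
             age = rep_len(age, length(ids)),
             sex = rep_len(sex, length(ids)),
             stringsAsFactors = FALSE)
}

# Small planted cohort used across tests.
small_cohort <- function(seed = 3, n_probes = 2000, n_sig = 40,
                         delta_beta = 0.2, n_controls = 60,
                         n_reference = 20) {
  simulate_cohort(cohort_config(n_probes = n_probes,
                                n_signature_probes = n_sig,
                                delta_beta = delta_beta,
                                n_controls = n_controls,
                                n_reference = n_reference, seed = seed))
}

case_ids_of <- function(sim) sim$sheet$sample_id[sim$sheet$group == "case"]
control_ids_of <- function(sim) sim$sheet$sample_id[sim$sheet$group == "control"]
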