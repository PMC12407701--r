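# Shared fixtures built in code at test time.

# short observation grid for cheap fitting tests
quick_times <- c(0, 12, 24, 48, 60, 72)

# a small, well-behaved dataset from the reference structure
quick_dataset <- function(cv = 0.1, replicates = 2, seed = 101,
                          model = named_models()$model_11574) {
  dplyr::select(
    generate_dataset(model, reference_params(model), quick_times,
                     replicates = replicates, cv = cv, seed = seed),
    -"experiment"
  )
}

# brute-force enumeration of all admissible production terms, independent of
# the library's generation order (oracle for enumerate_terms)
brute_force_term_signatures <- function(regulators) {
  sigs <- character()
  ab <- c(activation = "act", repression = "rep")
  for (r in regulators) {
    for (s in names(ab)) {
      sigs <- c(sigs, paste0(ab[s], "(", r, ")"),
                paste0(ab[s], "(", r, ")^2"))
    }
  }
  if (length(regulators) >= 2) {
    for (i in seq_along(regulators)) {
      for (j in seq_along(regulators)) {
        if (i >= j) next
        for (s1 in names(ab)) {
          for (s2 in names(ab)) {
            sigs <- c(sigs, paste0(ab[s1], "(", regulators[i], ")*",
                                   ab[s2], "(", regulators[j], ")"))
          }
        }
      }
    }
  }
  sort(sigs)
}
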