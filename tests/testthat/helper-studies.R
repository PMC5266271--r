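# shared builders for small in-memory studies

# a balanced study with B quartets, arms randomly permuted within block,
# outcomes drawn Bernoulli(p) independently of treatment unless `effect`
# shifts the PSS/PSSH-treated probability
make_balanced_study <- function(B, seed = 1, p = 0.5, effect = 0,
                                effect_on = "PSS") {
  set.seed(seed)
  n <- 4L * B
  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    block_id = rep(seq_len(B), each = 4L),
    arm = as.vector(vapply(seq_len(B), function(b) sample(arm_levels()),
                           character(4))),
    stringsAsFactors = FALSE
  )
  ind <- main_effect_indicator(units$arm, effect_on)
  prob <- pmin(pmax(p + effect * ind, 0.02), 0.98)
  for (oc in outcome_names()) units[[oc]] <- rbinom(n, 1, prob)
  units$know_pss <- rbinom(n, 1, 0.5)
  units$know_pssh <- rbinom(n, 1, 0.5)
  quartet_study(units)
}

# the closed form the balanced block-FE slope must equal: the across-block
# average of within-block treated-minus-control means
balanced_closed_form <- function(outcome, indicator, blocks) {
  mean(vapply(split(seq_along(outcome), blocks), function(idx) {
    mean(outcome[idx][indicator[idx] == 1]) -
      mean(outcome[idx][indicator[idx] == 0])
  }, numeric(1)))
}

# write a minimal valid outcome CSV and return its path
write_minimal_s1 <- function(path = tempfile(fileext = ".csv"),
                             arms = c("Ctrl", "Sel", "Store", "Sel+Store")) {
  header <- "treatment,sel1,sel2,store1,store2,gen1,gen2,block,know_sel,know_store"
  rows <- vapply(seq_along(arms), function(i) {
    paste(arms[i], "TRUE", "FALSE", "TRUE", "TRUE", "FALSE", "TRUE",
          1, "TRUE", "FALSE", sep = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}
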