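# in-code fixtures shared across test files

# six-site table with hand-checkable classes for every technique
toy_table <- function() {
  score_table(data.frame(
    section = "S1", site = as.character(1:6), icdas = c(0, 2, 2, 3, 5, 6),
    SW    = c(1, 2, 3, 3, 1, 2),
    SD    = c(1, 2, 3, 2, 1, 3),
    NFNBC = c(1, 2, 2, 3, 1, 2),
    NFBC  = c(1, 2, 2, 3, 2, 2),
    FBC   = c(1, 2, 2, 3, 1, 2),
    PLMQ  = c(1, 2, 2, NA, 1, 2)))
}

# random valid score table, optionally with missing cells
random_score_table <- function(n, seed, missing_rate = 0.1) {
  set.seed(seed)
  df <- data.frame(section = sprintf("S%d", ceiling(seq_len(n) / 6)),
                   site = as.character((seq_len(n) - 1) %% 6 + 1),
                   icdas = sample(0:6, n, replace = TRUE))
  for (tech in techniques()) {
    codes <- sample(technique_codes(tech), n, replace = TRUE)
    codes[runif(n) < missing_rate] <- NA
    df[[tech]] <- codes
  }
  score_table(df)
}

# independent oracle for binarize(): explicit per-site enumeration
brute_force_binarize <- function(table, combo, reaction, policy = "exclude_unscorable") {
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_len(nrow(table))) {
    tc <- table[[combo$test]][i]
    gc <- table[[combo$gold]][i]
    if (is.na(tc) || is.na(gc)) next
    t_cls <- to_canonical(combo$test, tc)
    g_cls <- to_canonical(combo$gold, gc)
    if (policy == "exclude_unscorable" &&
        !(g_cls %in% technique_vocabulary(combo$test))) next
    t_pos <- t_cls == reaction
    g_pos <- g_cls == reaction
    if (t_pos && g_pos) TP <- TP + 1L
    else if (t_pos) FP <- FP + 1L
    else if (g_pos) FN <- FN + 1L
    else TN <- TN + 1L
  }
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}

as_confusion_vector <- function(cc) {
  c(TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN)
}
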