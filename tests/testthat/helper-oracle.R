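# Brute-force LZ76 production-parsing oracle: at each word start, extend the
# word while a naive substring search finds it anywhere in the sequence
# ending before the current position (the "extended history"). Deliberately
# independent of the package's parser.
lz76_oracle <- function(s) {
  n <- length(s)
  c <- 0L
  l <- 1
  while (l <= n) {
    k <- 1
    repeat {
      if (l + k - 1 > n) break
      word <- s[l:(l + k - 1)]
      found <- FALSE
      if (l + k - 2 >= k) {
        for (st in 1:(l + k - 1 - k)) {
          if (all(s[st:(st + k - 1)] == word)) { found <- TRUE; break }
        }
      }
      if (!found) break
      k <- k + 1
    }
    c <- c + 1L
    l <- l + k
  }
  c
}

# all binary strings of length n as rows
all_binary_strings <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

# small labelled feature matrix with an optional planted class effect on the
# first feature, for exercising the CV machinery without EEG
toy_feature_matrix <- function(n_sf = 16, n_nsf = 10, n_feat = 8,
                               effect = 0, seed = 1) {
  withr::local_seed(seed)
  n <- n_sf + n_nsf
  labels <- c(rep("SF", n_sf), rep("NSF", n_nsf))
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  X[, 1] <- X[, 1] + effect * (labels == "NSF")
  structure(list(values = X, subject_ids = sprintf("S%03d", 1:n),
                 feature_names = colnames(X),
                 labels = factor(labels, levels = c("NSF", "SF")),
                 estimator = "lzc"),
            class = "feature_matrix")
}

# small synthetic cohort spec used across tests (2 epochs keeps it light)
tiny_spec <- function(n_sf = 8, n_nsf = 5, effect_size = 0.6, seed = 1,
                      n_epochs = 2) {
  cohort_spec(n_sf = n_sf, n_nsf = n_nsf, effect_size = effect_size,
              n_epochs_per_subject = n_epochs, seed = seed)
}
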