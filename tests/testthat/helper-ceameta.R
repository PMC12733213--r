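# shared fixtures and independent oracles

fixture <- function() load_records("mastaleru2025")

# a minimal consistent in-code study table
tiny_table <- function(n = 3) {
  as_study_table(data.frame(
    study_id = sprintf("T%02d", seq_len(n)),
    authors_label = "Test",
    pub_year = 2020 + seq_len(n),
    country = rep(c("Australia", "China", "Singapore"), length.out = n),
    intervention = rep(c("Inclisiran", "Inclisiran+statin"),
                       length.out = n),
    population_tag = "ASCVD",
    age_group = ">60",
    model_type = "markov",
    qaly_gain = seq_len(n) * 0.1,
    total_qaly = 10,
    total_cost = 30000 + seq_len(n) * 1000,
    incremental_cost = seq_len(n) * 1000,
    icer_per_qaly = (seq_len(n) * 1000) / (seq_len(n) * 0.1),
    currency_code = "PPP-USD",
    price_year = 2024,
    stringsAsFactors = FALSE), provenance = "test")
}

# brute-force DerSimonian-Laird oracle: explicit loops, shares no code
# with the package implementation
dl_oracle <- function(yi, sei) {
  k <- length(yi)
  w <- sw <- swy <- 0
  for (i in seq_len(k)) {
    wi <- 1 / sei[i]^2
    sw <- sw + wi
    swy <- swy + wi * yi[i]
  }
  mu_fe <- swy / sw
  Q <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    wi <- 1 / sei[i]^2
    Q <- Q + wi * (yi[i] - mu_fe)^2
    sw2 <- sw2 + wi^2
  }
  tau2 <- max(0, (Q - (k - 1)) / (sw - sw2 / sw))
  num <- den <- 0
  for (i in seq_len(k)) {
    ws <- 1 / (sei[i]^2 + tau2)
    num <- num + ws * yi[i]
    den <- den + ws
  }
  list(pooled = num / den, se = sqrt(1 / den), tau2 = tau2, Q = Q)
}

# normal-equations OLS oracle
ols_oracle <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))
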