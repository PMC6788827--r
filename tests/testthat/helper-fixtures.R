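# Shared fixtures: small montages, toy epoch builders, and the scaled-down
# replica study used by the structure-recovery checks.

# A reduced montage (CPz plus a ring of neighbours) for fast EEG simulation.
smallMontage <- function(n = 8) {
  m <- standardMontage32()
  keep <- c("CPz", "Cz", "CP3", "CP4", "Pz", "FCz", "P3", "P4",
            "C3", "C4", "Fz", "Oz")[seq_len(n)]
  m[match(keep, m$channel), ]
}

smallEEGParams <- function(n = 8, srate = 250, ...) {
  m <- smallMontage(n)
  eegParams(montage = m, srate_hz = srate,
            p3_topography = gaussianTopography(m, "CPz", 0.35),
            pe_topography = gaussianTopography(m, "CPz", 0.35), ...)
}

# Build an EpochSet directly from an array (trials x channels x samples).
toyEpochs <- function(data, srate = 250, t0 = -100, alignment = "stimulus",
                      channels = NULL) {
  dm <- dim(data)
  dt <- 1000 / srate
  EpochSet(data, seq(t0, by = dt, length.out = dm[3]), alignment,
           channels %||% paste0("ch", seq_len(dm[2])), srate, seq_len(dm[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One simulated subject of the scaled-down replica study: 320 trials,
# post-response-only confidence coupling unless overridden.
simulateReplicaSubject <- function(s, eeg_params, n_blocks = 5) {
  d <- makeDesign(n_blocks = n_blocks, participant = s, seed = 100 + s)
  tr <- simulateObserver(d, seed = 200 + s)
  ep <- simulateEEG(tr, eeg_params, seed = 300 + s)
  resp <- rejectExtreme(baselineCorrect(ep$response, c(-100, 0)))$epochs
  stim <- rejectExtreme(baselineCorrect(ep$stimulus, c(-100, 0)))$epochs
  list(trials = tr, resp = resp, stim = stim)
}

# Index sets and labels of the decoding analyses for one subject: training
# on no-choice trials correct on both decisions (confidence median split),
# testing on correct free-choice trials (see-again choices; "high" when the
# observer sought information, i.e. low confidence).
replicaIndexSets <- function(sub, epochs) {
  tr <- sub$trials
  ti <- trialIndex(epochs)
  nc <- which(tr$trial_type[ti] == "no-choice" & tr$primary_correct[ti] == 1 &
                tr$final_correct[ti] == 1)
  fc <- which(tr$trial_type[ti] == "free" & tr$primary_correct[ti] == 1)
  list(nc = nc, fc = fc,
       conf = medianSplit(tr$confidence_z[ti][nc]),
       seek = ifelse(tr$see_again[ti][fc] == 1, "high", "low"))
}
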