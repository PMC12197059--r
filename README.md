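# earvitals

Physiological monitoring from in-ear audio. A microphone sealed in the ear
canal hears a faint mixture of breathing noise, bone-conducted heart sound,
footstep impacts and ambient noise; `earvitals` estimates heart rate,
respiratory rate and breathing-phase structure from such recordings. It is
aimed at researchers in wearable physiological sensing and audio-based
health monitoring who need a tested, fully seeded reference implementation
to build on — including a synthetic-data generator with exact ground truth,
since real in-ear datasets are rarely shareable.

## Method

1. **Segment selection.** Band-pass 500–8000 Hz (4th-order zero-phase
   Butterworth), dual-threshold endpoint detection on 10 ms short-time
   energy and zero-crossing rate (5 consecutive frames above threshold open
   a fixed 15 s segment), then a periodicity gate: the decimated Hilbert
   envelope is autocorrelated and the segment is kept only if the mean
   peak spacing T̂ = mean(diff(peak lags))/fs falls in a closed interval
   [d1, d2].
2. **Separation.** Template-constrained semi-supervised NMF on the
   magnitude spectrogram: V ≈ W H with W = [Wb | Wh | Wn | Wun], the
   breath/heart/noise blocks learned from clean reference recordings
   (unit-norm columns, frozen) plus a small free block. The objective is
   the generalized KL divergence with L1 activation penalties,
   D(V | WH) + Σ_k μ_k‖H_k‖₁, minimized by multiplicative updates that
   provably never increase the cost. Soft masks
   mask_src = (W_src H_src)/(WH) are applied to the mixture magnitude and
   inverted with the original phase.
3. **Breathing phases.** Frame RMS → logistic activity probability
   (p = plogis(RMS − τ), τ auto-calibrated) → two-state Viterbi decoding
   (ACTIVE self-transition 0.55, uniform pause row) → alternating
   INHALE/EXHALE assignment of active runs. Optional learned models: a
   one-layer CNN breath gate (ten 12×12 filters) and an attention-BiLSTM
   per-step phase classifier, both implemented from scratch with
   gradient-checked backpropagation.
4. **Vitals.** Heart rate = 60·count/duration from dual-threshold beat
   segmentation (0.25 s refractory merging each S1/S2 pair, with
   periodicity-robust counting); respiratory rate and inhale:exhale ratio
   from the phase track. Separation quality is scored with SDR / SIR /
   SI-SDR against the convolutive ground-truth source images.

## Worked example

Everything below is seeded and reproducible.

```r
library(earvitals)

# templates from clean synthetic references (30 s per source)
bank <- learn_templates(
  list(breath = gen_breath(30, br_bpm = 14, seed = 900001)$audio,
       heart  = gen_heartbeat(30, hr_bpm = 80, seed = 900002)$audio,
       noise  = gen_noise(30, "footsteps", seed = 900003)),
  max_iter = 100, seed = 7)

# a 32 s convolutive mixture: 96 bpm heart, 18 breaths/min breathing,
# footstep noise, random length-4 FIR mixing filters
item <- make_corpus(1, corpus_config(duration_s = 32, hr_bpm = 96,
                                     br_bpm = 18), seed = 501)[[1]]

res <- run_pipeline(item$mixture, bank,
                    config = pipeline_config(seed = 1,
                                             preprocess = list(d2 = 8)))
print(res)
#> <pipeline_result: ok, 2/2 segments accepted>
#> <vitals_report: hr 96.0 bpm, br 18.0 breaths/min, ratio 1.26>
#> <vitals_report: hr 96.0 bpm, br 18.0 breaths/min, ratio 1.27 [nmf-not-converged]>
```

Both accepted 15 s segments recover the configured 96 bpm and
18 breaths/min exactly; the inhale:exhale ratio (generator truth 1.0) drifts
to about 1.26 because the two phases recover with unequal amplitude after
separation. The `nmf-not-converged` flag records that the second segment hit
the iteration cap before the relative-change tolerance. Separation quality
on the same item:

```r
sep <- separate(item$mixture, bank, sep_config(seed = 1))
si_sdr(item$truth$images$breath, sep$audio_breath) -
  si_sdr(item$truth$images$breath, item$mixture)
#> [1] 13.59873
```

i.e. the breath estimate improves on the raw mixture by about 13.6 dB
SI-SDR relative to the true breath source image.

## Package layout

- `R/signal_io.R` — WAV (PCM16/24, float32) and label-CSV carriers
- `R/preprocess.R` — band-pass, energy/ZCR detection, envelope, period gate
- `R/stft.R`, `R/nmf.R` — STFT/ISTFT and the semi-supervised KL-NMF
- `R/features.R` — MFCC and logMel on the 87-steps-per-second grid
- `R/viterbi.R`, `R/bem.R`, `R/bpdm.R` — phase labeling and learned models
- `R/vitals.R` — beat segmentation, heart/respiratory rates, breath ratio
- `R/synthetic.R` — seeded generators and convolutive mixing
- `R/metrics.R` — BSS decomposition, SDR/SIR/SI-SDR, accuracy/recall/MAE
- `R/pipeline.R` — end-to-end pipeline with provenance-carrying reports
- `inst/cli/earvitals` — thin command-line wrapper (synth, preprocess,
  separate, label, train-bpdm, phases, vitals, run, evaluate, …)
- `vignettes/earvitals-methods.Rmd` — the full methods account
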