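# librepulse

Fat suppression for whole-heart coronary MR angiography at 3 T, on the
desk: design and characterization of **LIBRE** (lipid-insensitive binomial
off-resonant excitation) radiofrequency pulses, Bloch-equation comparison
against CHESS fat saturation (FS) and binomial 1–180°–1 water excitation
(WE) in a segmented spoiled-GRE acquisition, and a virtual 3D radial
imaging pipeline (spiral phyllotaxis trajectory, digital phantoms, gridding
reconstruction, SI projections) with the image-quality metrics used to
compare the schemes (SNR, CNR, vessel sharpness, vessel length).

It is aimed at MR physicists and sequence developers who want a
reproducible, fully simulated account of why an off-resonant binomial pulse
suppresses fat over a much wider band than conventional approaches.

## The core model

A LIBRE pulse is a pair of rectangular sub-pulses of duration τ played at a
carrier frequency f_RF above water. Fat at f_fat is nulled when each
sub-pulse rotates the fat magnetization through a full turn about its
effective field, which ties the parameters together:

    τ = sqrt(1 − (α/2π)²) / (f_RF − f_fat),   α in radians

The package solves this in both directions, builds executable waveforms for
all three schemes, propagates them through the Bloch equations (24
excitations, TR 5.1 ms, perfect spoiling), and extracts the
fat-suppression bandwidth: the width of the frequency interval over which
the aggregated transverse magnetization stays at or below 10% of the row
maximum.

## Worked example

```r
library(librepulse)

# optimal carrier frequency for a 1.1 ms sub-pulse, fat at -440 Hz
round(solve_optimal_frf(1.1e-3, 10, -440))
#> [1] 469

# the corresponding waveform lasts 2 x 1.1 ms
make_libre(18, 479, 1.1e-3)$total_duration_s
#> [1] 0.0022

# fat-suppression bandwidths of the three schemes at 18 degrees
bandwidth_benchmark()
#>   method bandwidth_hz
#> 1  LIBRE    247.44315
#> 2     FS    135.17417
#> 3     WE     34.05088
```

The benchmark numbers mean: under the reference protocol (TR 5.1 ms, 24
excitations per segment, blood T1/T2 = 1932/275 ms with a lipid pool of
290/100 ms around the fat resonance, segment-averaged signal), LIBRE keeps
fat below 10% of the water signal over ~247 Hz around −440 Hz — roughly
seven times the width of the WE null (~34 Hz) and nearly twice that of the
CHESS prepulse (~135 Hz). That ordering is the quantitative reason LIBRE
tolerates the B0 inhomogeneity of a large field of view where the other two
schemes fail. See `vignettes/libre-methods.Rmd` for the modeling choices
behind these numbers and their sensitivity.

A command-line interface wrapping the same functions is installed at
`inst/cli/librepulse`:

```sh
Rscript inst/cli/librepulse optimal-frf --tau-ms 1.1 --alpha 10 --f-fat -440
Rscript inst/cli/librepulse traj --segments 500 --lines 24 --out out/
```

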