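# graphomotor

Bayesian perception and production of single-stroke cursive letters from
one shared internal representation.

## The problem

How can the same stored knowledge of a letter serve to *read* it, to
*write* it with an arm, to *copy* an arbitrary trace, and to read better
by *imagining the movement* that produced a trace?  `graphomotor` models
all of these with a single generative representation: a letter, for a
given writer, is an ordered sequence of **via-points** — landmarks placed
where the horizontal or vertical pen velocity is zero (horizontal and
vertical tangents), at cusps, and at the stroke's start and end.  Each
via-point is four-dimensional, (x, y, vx, vy).

Knowledge is probabilistic.  Via-points are discretized (positions on 41
bins 0–40, velocities on 7 bins −3..3) and, per writer `w`, letter
`l`, via-point index `j`, and dimension independently, the model stores
first-order Markov tables estimated as binomially smoothed **Laplace
succession laws**

    P(v) = (n_v + 1) / (n + K),

never zero, uniform before any data.  A sequence scores as

    log P(N | l, w) + sum_j sum_d log P(v_jd | v_(j-1)d, l, w),

and Bayesian inversion of this one generative story yields the tasks:
letter recognition (writer known or marginalized), writer recognition,
joint recognition, letter writing through minimum-acceleration (cubic
Hermite) segments and a simulated two-joint arm, model-free trajectory
copying, letter copying with style transfer, and recognition aided by
internal motor simulation (the posterior is the normalized product of a
perception likelihood and a re-perceived-simulation likelihood).

Because no public handwriting corpus accompanies the model, the package
includes a first-class synthetic-writer module: hand-designed via-point
skeletons for the 22 pen-down lowercase letters, parametric writer
styles (slant, scale, roundness, jitter, allographs), and a seeded,
bit-reproducible corpus builder realizing the 4 writers x 22 letters x
40 trials reference design (3,520 trajectories).

It is intended for researchers in computational motor control and
perception–action modelling who want a complete, testable implementation
of the via-point account to probe, extend, or compare against.

## A worked example

```r
library(graphomotor)

corpus <- build_corpus(seed = 20211)   # 4 writers x 22 letters x 40 trials
corpus
#> <writing_corpus> 3520 trajectories: 4 writers x 22 letters x 40 trials

model <- fit_corpus_model(corpus)
model
#> <letter_model> 22 letters x 4 writers, 3520 observed sequences
#>   letters: a b c d e f g h k l m n o p q r s u v w y z
#>   writers: upright slanted rounded cramped

trial <- corpus$trajectories[[
  which(corpus$labels$letter == "g" & corpus$labels$writer == "slanted")[1]]]
extract_viapoints(trial)
#> <viapoint_seq> 8 points
#>        x         y         vx         vy               kind sample_index
#> 1 27.844 25.540635 -7.061e-01  2.144e-01              start         1.00
#> 2 20.072 27.099037 -1.072e+00 -4.077e-17 horizontal_tangent        11.89
#> 3  8.263 18.565294  1.388e-16 -8.670e-01   vertical_tangent        30.87
#> 4 15.565 12.049182  9.397e-01  1.596e-16 horizontal_tangent        44.07
#> 5 29.023 26.110624 -5.917e-02  1.143e-01               cusp        69.94
#> 6 16.146  0.009917 -8.982e-01 -9.333e-16 horizontal_tangent       107.86
#> 7 10.798  6.181279  1.173e-15  4.620e-01   vertical_tangent       118.57
#> 8 22.856  8.459231  8.606e-01  2.261e-02                end       135.00

recognize_letter(trial, model)        # writer unknown: marginalized
#> <task_result> answer: g
#>   top posterior: g=1.000 q=0.000 a=0.000 d=0.000 c=0.000
```

The extractor found the letter's oval (tangents and the closing cusp)
and its descender loop; the posterior concentrates on `g`, with the
residual mass on the structurally similar `q`, `a`, `d`.  The loop also
closes in the other direction — the model writes, and reads its own
writing:

```r
w <- write_letter("g", "rounded", model, seed = 42,
                  effector = two_joint_arm())
round(sort(recognize_letter(w$trajectory, model, "rounded")$posterior,
           decreasing = TRUE)[1:3], 4)
#>      g      q      d
#> 0.9998 0.0002 0.0000
```

`w$arm_trajectory` holds the same letter as written by double-integrating
joint accelerations through the two-joint arm.

A command-line interface wrapping the same functions (subcommands
`build-corpus`, `fit`, `recognize`, `recognize-writer`, `write`,
`copy-traj`, `copy-letter`, `recognize-sim`, `eval`, `audit-params`) is
installed at `inst/scripts/graphomotor`.

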