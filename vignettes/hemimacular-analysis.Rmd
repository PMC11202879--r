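---
title: "Lateralizing retrochiasmal lesions from hemi-macular GCL/IPL atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralizing retrochiasmal lesions from hemi-macular GCL/IPL atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemimacula)
library(dplyr)
```

## The problem

Lesions of the retrochiasmal visual pathway (optic tract, lateral geniculate
nucleus, optic radiations) are common in multiple sclerosis (MS) but often
asymptomatic: standard automated perimetry misses most of them, and MRI is
costly to repeat. Because the right hemi-retinae of both eyes project to the
right retrochiasmal pathway, a posterior lesion produces — through retrograde
trans-synaptic degeneration across the geniculate synapse — *homonymous*
thinning of the macular ganglion cell layer (GCL) and inner plexiform layer
(IPL): the hemi-macula on the lesion side thins in **both** eyes. Macular OCT
can therefore both detect and lateralize such lesions.

This package implements that analysis as a reproducible pipeline:

1. a grid model for posterior-pole 8×8 sector-thickness charts, with explicit
   laterality and orientation conventions and central 4×4 extraction;
2. a two-step thickness correction (control-mean centering plus an additive
   per-sector optic-neuritis offset);
3. a deterministic hemi-macular atrophy classifier producing patient-level
   and eye-level lesion calls with side;
4. paired diagnostic-accuracy evaluation against MRI and visual-field (VF)
   labels (sensitivity, specificity, PPV, NPV, McNemar tests), plus an audit
   utility that reconstructs candidate integer contingency tables from
   rounded published statistics;
5. a synthetic cohort generator that encodes the damage structure the
   analysis assumes, so every stage is testable without patient data.

## Grid model and conventions

Grids are long-format tibbles (one row per sector) with 1-based `row`/`col`
indices, row 1 = superior retina. Only the 16 centermost sectors of the 8×8
chart — rows and columns 3–6, the symmetric center — enter the analysis;
`extract_central()` renumbers them 1–4. This is the only symmetric choice of
"central 4×4" and matches how the central grid is marked on the device
printout.

Laterality is the subtle part. Hemi-macula queries are defined in *patient
space*: anatomical right vs left of the vertical meridian. Posterior-pole
maps are taken to be fundus view with image-right = patient's anatomical
right for both eyes (the default `"standard"` display convention), which
makes "right hemi-macula" literally the right half of the grid: the temporal
half of OD and the nasal half of OS (`hemi_label()`). Vendors that mirror
left-eye maps are handled by the `"mirrored_os"` convention, which reverses
OS columns on ingest; applying that transform twice is the identity, which
the tests exercise. Superior/inferior orientation never enters the rules
(hemi-maculae are vertical-meridian halves) but is fixed for
reproducibility.

A hemi-macula with up to 2 of its 8 sectors missing can still be classified;
more missing sectors make it unevaluable and the eye is excluded with a
logged reason. This partial-data rule is our own: source studies exclude
poor-quality scans outright and state no partial rule.

## The two-step correction

For each layer, per sector \(s\):

* **Baseline adjustment** — \(\tau_s = t_s - \mu_s\), where \(\mu_s\) is the
  control-group mean (both eyes of all controls pooled; sample SD with
  \(n-1\)). Healthy maps are thereby centered at zero.
* **ON adjustment** (eyes with optic neuritis history only) —
  \(\tau_s \leftarrow \tau_s + \delta_s\), where
  \(\delta_s = \overline{t_s}^{\,\text{ref}} - \overline{t_s}^{\,\text{ON}}\)
  is the mean reference-minus-ON difference, positive where ON eyes are
  thinner. ON causes diffuse inner-retinal thinning in the affected eye;
  adding \(\delta_s\) removes that component so residual deviations reflect
  retrochiasmal damage.

Two choices here were genuinely open and are config-exposed:

* `on_reference`: the offset can be computed against healthy controls
  (default) or against MS eyes without ON history. Both are defensible; the
  default follows the definition used when the offset is introduced as a
  methods step rather than summarized afterwards.
* `on_scope`: ON is an eye-level event, so the default fits the offset from
  (and applies it to) ON eyes only (`"eye"`); `"patient"` treats both eyes
  of an ON-history patient as exposed.

Pooling both eyes of a control into the reference treats eyes as
independent; inter-eye correlation is a documented simplification. The
correction refuses to run twice on the same eye (state error, never a silent
doubling), and in simulation restores corrected ON-eye sector means to the
reference means — an identity the acceptance tests verify on held-out eyes
at 500 eyes per arm within 3 standard errors.

## The atrophy classifier

Clinically the deviation maps are read by two masked ophthalmologists who
reach consensus. The package replaces the readers with a deterministic
surrogate with two parameters, both reported in every output:

* a sector is **flagged** when \(\tau_s \le -k\,\sigma_s\) with \(\sigma_s\)
  the control SD of that sector; default \(k = 2\) (≈ 2.3rd percentile under
  normality). A degenerate \(\sigma_s = 0\) flags any strictly negative
  deviation, with a warning.
* a hemi-macula is **atrophic** when ≥ `m` of its 8 sectors are flagged;
  default `m = 4` (half the hemi-field, a middle value between a single
  noisy sector and demanding the full field).

A retrochiasmal lesion on side \(x\) is called for a layer iff the side-\(x\)
hemi-macula is atrophic in **both** eyes; both sides give `bilateral`; the
combined call unions GCL and IPL (an alteration in either suffices). A
bilateral call counts as test-positive, and when matched against an MRI side
it matches either side — the downstream contingency analysis is
presence/absence. Increasing \(k\) or \(m\) can only remove flags or calls,
so sensitivity is monotonically non-increasing in both — a property the
acceptance tests check on a fixed noisy cohort.

Eye-level analysis: for patients with a lateralized MRI lesion, each eye is
ipsilateral or contralateral to the lesion, and is positive iff its
lesion-side hemi-macula is atrophic. Because roughly 53% of chiasmal fibers
cross, the contralateral eye receives the larger share of the trans-synaptic
damage and is expected to be detected more often.

## Diagnostic evaluation

`run_all()` evaluates, over the MS patients (controls only inform the
reference):

* OCT vs MRI at patient level, per layer × {raw, ON-corrected} — "raw" maps
  are still baseline-centered, since the flags need the \(\sigma_s\) scale;
* VF vs MRI (one row) — VF records with ≥ 33% fixation losses, false
  positives or false negatives are unreliable and excluded; a patient leaves
  the VF comparisons if either eye is unreliable. Patient-level VF
  positivity defaults to the recorded per-patient verdict (equivalently,
  either eye positive); `"both_eyes"` aggregation is available;
* OCT vs VF, per layer × variant;
* OCT vs MRI at eye level, per layer × variant × {ipsilateral,
  contralateral}. Published eye-level tables report specificity without
  stating which eyes act as reference-negatives; our construction takes the
  relation-matched eyes of MRI-lesioned patients as reference-positives and
  all eyes of MRI-negative patients (index = atrophy of either hemi-macula)
  as the shared reference-negative pool.

Each row carries the 2×2 cell counts, sensitivity, specificity, PPV, NPV
(undefined denominators propagate as explicit `NA`, never zero), and a
McNemar p-value. The McNemar default is the exact binomial test when
\(b + c < 25\) discordant pairs and the uncorrected chi-square
\((b-c)^2/(b+c)\) otherwise; the continuity-corrected variant
\((|b-c|-1)^2/(b+c)\) is also exposed and applies the correction
unconditionally (unlike `stats::mcnemar.test()`, which silently drops it
when \(b = c\)).

`reconstruct_tables()` addresses a reporting audit: four statistics rounded
to two decimals rarely determine the integer cells. It enumerates all tables
of a given total whose statistics round (half-up, matching clinical table
formatting) to the published values — possibly none (inconsistent rounding)
or many (under-determined). Its soundness property,
`reconstruct_tables(diag_stats(T), total(T)) ∋ T`, is tested on 500 random
tables.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the analysis was designed
for; the defaults in `sim_params()` *are* those conditions, not tuning
knobs:

| parameter | default | rationale |
|---|---|---|
| `n_patients`, `n_controls` | 52, 27 | the study's cohort sizes |
| `p_on_history` | 0.307 | reported ON-history rate (16/52) |
| `p_lesion` | 0.60 | lesion prevalence is unreported; 0.60 sits inside the 30–90% span of retrochiasmal demyelinating lesions reported across MRI series |
| `crossed_fraction` | 0.53 | ≈ 53% crossed vs 47% uncrossed chiasmal fibers |
| `vf_sens`, `vf_false_pos` | 0.14, 0.38 | anchors the VF-vs-lesion behavior to the reported VF sensitivity/specificity (0.14/0.62) |
| `base_mean` | GCL 30–52 µm, IPL 28–44 µm | center-weighted healthy sector means in the range Spectralis segmentation reports |
| `base_sd` | 4 µm | realistic between-eye sector variability |
| `on_effect` | GCL 8, IPL 6 µm | diffuse post-ON thinning, literature-plausible |
| `lesion_effect` | GCL 10, IPL 8 µm | mean hemi-macular trans-synaptic deficit; the true study magnitude is unreported, so these are literature-plausible placeholders, never estimates of the study's data |
| `age_*` | 35.07 ± 12.73 / 31.85 ± 10.97 | reported group demographics |

Mechanics: sector thicknesses are independent Gaussians around the layer
base means (the 4×4 block border-replicated to the full 8×8 chart); ON
patients have one randomly chosen affected eye thinned diffusely; lesioned
patients lose, from the lesion-side hemi-macula of each eye,
`2 · lesion_effect · crossed_fraction` µm in the contralateral eye and
`2 · lesion_effect · (1 − crossed_fraction)` µm in the ipsilateral eye — the
across-eye mean deficit is exactly `lesion_effect`, and the
contralateral:ipsilateral ratio is 53:47. The VF verdict is generated at
patient level (that is how it is compared against MRI) and copied to both
eyes in the record format; 5% of eyes get an unreliable VF so the
reliability filter stays exercised. Values are clamped to [0, 200] µm.

What the generator deliberately does **not** emulate: spatial
autocorrelation between sectors, segmentation artifacts, microcystic inner
nuclear layer edema, bilateral ON, partial (sub-hemi) field defects, and any
longitudinal dynamics. Passing tests therefore show that the pipeline
recovers the assumed damage structure, not that the classifier's operating
point transfers to real Spectralis exports.

`calibration_check()` re-derives the generator's own anchors empirically
(ON fraction, lesion prevalence, VF sensitivity/specificity, hemi-deficits
by eye relation, implied crossed fraction); deficits are measured on non-ON
eyes of lesioned patients so the ON effect cannot contaminate the estimate.

## Numerical and scale choices

* Determinism: cohorts are bit-reproducible from `seed`
  (`withr::with_seed`); `run_all()` is deterministic given cohort + config.
* The correction model serializes to JSON at 17 significant digits, which
  round-trips doubles exactly.
* Statistics oracles in the test suite are brute-force (elementwise
  comparison, counting loops, full binomial enumeration) and agree with the
  implementation to 1e-12.
* Problem sizes used by the test suite: 1,000 random paired datasets
  (n ≤ 200) for the oracle checks; 500 eyes per arm for the
  correction-identity check; the default 52 + 27 cohort for classifier
  recovery; 100 small cohorts (8 patients, 4 controls) for the
  laterality-mirror property; 10,000 patients for generator calibration;
  500 random tables (total ≤ 60) for reconstruction soundness. These sizes
  give comfortable Monte-Carlo margins at the stated 3-SE tolerances while
  keeping the whole suite in a couple of minutes on one CPU.

## Worked example

```{r example}
cohort <- simulate_cohort(sim_params(), seed = 1)
cohort

ev <- run_all(cohort, pipeline_config(k = 2, m = 4))
tidy(ev) |>
  select(comparison, n, sensitivity, specificity, ppv, npv, mcnemar_p) |>
  print(n = Inf)
glance(ev)
```

With the default noise level the classifier shows the qualitative pattern
the method predicts: moderate sensitivity, high specificity and PPV at
patient level, and stronger detection in contralateral than ipsilateral
eyes.

```{r plot, fig.width = 7, fig.height = 5}
autoplot(ev)
```

## Known limitations

* The (k, m) reader surrogate is our construction; published results came
  from human consensus reading, so agreement in operating point is not
  implied. Both parameters are reported with every output, and a
  "second-reader" style robustness check is simply a re-run with perturbed
  (k, m).
* The eye-level reference-negative convention (above) is one of several
  defensible constructions.
* Sector independence in the generator understates the effective noise
  correlation of real maps; hemi-level counts on real data will be more
  clustered than simulated ones.
* No age/sex covariate adjustment (matched controls are assumed) and no
  longitudinal modelling.
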