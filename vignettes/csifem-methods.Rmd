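---
title: "Methods: contrast source inversion with edge-element FEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast source inversion with edge-element FEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The imaging problem

Microwave imaging of the head aims to reconstruct the spatial distribution
of the complex relative permittivity
$\tilde\epsilon_r(\mathbf r) = \epsilon_r - j\sigma/(\omega\epsilon_0)$
from scattering measurements taken by an array of antennas surrounding the
head through a coupling medium.  A haemorrhagic stroke is a blood-filled
region (at 1 GHz, blood has $\epsilon_r = 64.41$, $\sigma = 1.58$ S/m),
dielectrically distinct from the surrounding tissue, so a quantitative
reconstruction of $(\epsilon_r, \sigma)$ localizes it.

The package works with the exp($+j\omega t$) convention, so passive media
have $\mathrm{Im}\,\tilde\epsilon \le 0$.  All quantities are in SI units
(metres, Hz, S/m).

# Contrast source inversion

Two unknowns are iterated: the **dielectric contrast**
$$\chi(\mathbf r) = \frac{\tilde\epsilon_r(\mathbf r) -
\epsilon_b(\mathbf r)}{\epsilon_b(\mathbf r)},$$
relative to the known background $\epsilon_b$, and the per-transmitter
**contrast sources** $\boldsymbol\omega_t = \chi\,\mathbf E_t^{tot}$, the
equivalent induced currents that radiate the scattered field.  The
scattered field solves the background wave equation
$$\nabla\times\nabla\times\mathbf E_t^{sct} - k_b^2\,\mathbf E_t^{sct}
  = k_b^2\,\boldsymbol\omega_t,
\qquad k_b^2 = \omega^2\mu_0\epsilon_0\epsilon_b .$$

CSI minimizes the two-term functional
$F_{CSI} = F_S + F_D$, where $F_S$ is the normalized data misfit at the
antennas (through the operator $G_S$, which radiates a contrast source and
samples it at the receivers) and $F_D$ the normalized residual of the
object equation $\boldsymbol\omega_t = \chi(\mathbf E_t^{inc} +
G_D\boldsymbol\omega_t)$ in the imaging volume.  At $\omega = 0$ the data
term is exactly 1 and the object term is undefined, which is why the
iteration starts from a backpropagation guess rather than zero.

# Discretization

The domain is a box meshed into tetrahedra (each hexahedral cell of a
structured grid split into six tetrahedra by the Kuhn rule, which makes
uniform refinement nested and conforming).  Fields are expanded in
lowest-order curl-conforming (Whitney) edge elements: one complex
coefficient per mesh edge, unit circulation along the owning edge,
tangential continuity across faces.  The permittivity is sampled at each
cell barycenter and taken constant per cell.  Stiffness ($\nabla\times$
products), mass ($k_b^2$-weighted products) and the first-order absorbing
boundary term are assembled from closed-form element integrals; products
of barycentric coordinates integrate to $V/20\,(1+\delta_{pq})$, so no
numerical quadrature enters the operators (the test suite checks every
closed form against independent quadrature rules).

Two discretizations of the contrast source are implemented side by side:

* **per-cell vector coefficients** (the standard choice): one complex
  3-vector per cell, tied to the total field evaluated at the barycenter.
  The coupling to the wave equation is a vector matrix whose entries are
  $k_b^2\int_{C_i}\mathbf N_m\,d^3r$.
* **edge-basis scalar coefficients**: the contrast source is expanded in
  the field's own basis functions windowed cell-wise by the pulse
  function, giving $6I$ scalar coefficients $\omega_{t,(i,e)} =
  \chi_i\,E^{tot}_{t,e}$.  The coupling matrix entries are
  $k_b^2\int_{C_i}\mathbf N_m\cdot\mathbf N_e\,d^3r$ — exactly the
  cell-wise mass blocks.

The edge-basis representation is *exactly consistent*: because
$k_b^2\chi = k^2 - k_b^2$ cell-wise, the coupling matrix applied to the
exact contrast sources reproduces $(V_{target} - V_{background})\,e^{tot}$
identically, so the discretized wave equation at the exact solution is
satisfied up to the forward-solver floor alone.  The per-cell variant
freezes amplitude and direction of the source inside each cell and carries
a genuine discretization error.  A third mode ("barycenter") evaluates the
edge-basis source functions at the cell barycenter; it is algebraically
identical to the per-cell vector discretization (the test suite asserts
this), which lets the inversion run both discretizations through one code
path, differing only in the coupling matrix.

# Acquisition models

The default acquisition is an equatorial ring of elementary electric
dipoles (z-polarized), each acting as transmitter and receiver; the
measurement functional samples the polarization component of the field at
the receiver positions.  An annular TEM coaxial-port model is also
provided: the normalized mode $\mathbf e_{TEM} =
\hat\rho/(\rho\sqrt{2\pi\ln(r_b/r_a)})$, its tensor-product quadrature
over the annulus, projection of fields onto the mode, the S-parameter
conversion rules (with the impressed wave subtracted at the transmitting
port), and scattered data as the S-parameter difference between the
scenario under test and the background.  Both models reduce to a sparse
measurement matrix plus an excitation right-hand side, and the inversion
is agnostic to which produced the data.  The port model idealizes the
antenna as an annular aperture carrying only the TEM mode; no waveguide
termination, higher modes, or cable de-embedding are modelled.

# The inversion iteration

The update equations follow the canonical CSI scheme: one Polak-Ribière
conjugate-gradient step per transmitter on the contrast sources with a
closed-form exact line search (the functional is quadratic along the
search direction), followed by the cell-wise least-squares contrast
update
$$\chi_i = \frac{\sum_t \langle \mathbf E_{t,i}, \omega_{t,i}\rangle}
               {\sum_t \lVert \mathbf E_{t,i}\rVert^2},
\qquad \mathbf E_t = \mathbf E_t^{inc} + G_D\boldsymbol\omega_t,$$
restricted to the domain-of-interest mask.  Cells whose field-energy
denominator falls below $10^{-30}$ keep their previous contrast.  The
backpropagation initial guess is $\gamma_t\,G_S^H d_t$ with the
one-parameter minimizer $\gamma_t = \lVert G_S^H d_t\rVert^2 /
\lVert G_S G_S^H d_t\rVert^2$.  The object-term normalization
$\sum_t\lVert\chi\,\mathbf E^{inc}_t\rVert^2$ is recomputed with the
current contrast at the start of every iteration (the canonical choice;
whether the original scheme froze it is not documented).  The iteration
aborts with a diagnostic if the cost increases five times in a row.

Per iteration and transmitter, the loop costs one forward and one adjoint
solve with the cached background factorization; data residuals, radiated
fields and line-search quantities are updated incrementally.

# Solving the discretized wave equation

The system $U - V - A_{abc}$ is complex-symmetric.  R's sparse
infrastructure has no complex factorizations, and the real $2n\times 2n$
block equivalent is far too expensive for the left-looking scalar LU
available there, so the package carries its own direct solver: a
supernodal complex-symmetric $LDL^T$ factorization.  The fill-reducing
ordering and supernode partition are taken from CHOLMOD's supernodal
Cholesky of a symmetric positive-definite proxy carried on the same
sparsity pattern; the numeric phase runs in compiled code with
BLAS-blocked panel updates (`zgemm`/`ztrsm`).  Pivoting is static —
near-zero diagonal pivots are perturbed at a relative threshold of
$10^{-14}$ and counted — and every forward solve is wrapped in iterative
refinement against the assembled operator, with a hard error if the
requested residual (default $10^{-12}$ relative) cannot be met.  On the
reference head fixture (160,804 edges) no static pivots are triggered and
unrefined residuals sit near $10^{-13}$.

Krylov alternatives (shifted-SPD-preconditioned COCG and flexible GMRES,
two-grid and damped coarse-grid corrections) were evaluated and rejected:
at these frequencies the preconditioned spectra carry a dense cloud of
near-zero eigenvalues that defeats restarted and even long-recurrence
iterations well before the $10^{-12}$ tolerance the consistency
experiments need.

Tiny systems (up to 800 edges) use a sparse LU of the real block form
instead; both backends are exact, deterministic, and interchangeable
behind one interface.  A curl-conforming interpolation operator between
nested meshes (line integrals of the coarse Whitney field along fine
edges) is exported as a general utility.

# The synthetic-scenario generator

`phantom_spec()` describes concentric sphere/ellipsoid layers (outermost
first, later layers override) in a coupling medium; `stroke_spec()` adds
a blood-like ellipsoidal inclusion (defaults $\epsilon_r = 64.41$,
$\sigma = 1.58$ S/m).  Cells are classified by their barycenter.  The
default desk-scale geometry is a homogeneous 50 mm head sphere with the
head-average properties $\epsilon_r = 45.37$, $\sigma = 0.77$ S/m in a
140 mm box of $\epsilon_r = 20$ coupling medium at 1 GHz, with 8 dipole
antennas on a 60 mm equatorial ring, a 4 mm data mesh and a 5 mm
inversion mesh.  `generate_dataset()` forward-solves background and
target scenarios on the *data* mesh, samples the receivers, and prepares
the incident field and factorized background operators on the different
*inversion* mesh; asking for identical meshes triggers an "inverse crime"
warning unless explicitly overridden.  Optional measurement noise is
complex circular Gaussian per data entry, scaled per transmitter to a
requested SNR in dB and driven by an explicit integer seed; the default
is noiseless (the original study's noise treatment for the synthetic
inversion is not documented).  The generator emulates layered geometry,
contrast levels, acquisition layout and mesh mismatch; it does not emulate
anatomical tissue maps, antenna feed structures, dispersion across
frequency, or measurement calibration errors, so passing tests demonstrate
correctness of the algorithmic chain, not clinical performance.

The ellipsoidal inclusion replaces the anatomically realistic stroke
shape of imaging-derived phantoms; shape realism is irrelevant to the
discretization questions the package addresses.

# Diagnostics

`consistency_study()` reproduces the discretization-accuracy experiments
on a single mesh: the wave-equation residual norms $\eta$ (Euclidean) and
$\eta_r$ (relative), the scattered-field recovery error, and the cost
terms $F_S$, $F_D$ evaluated at the exact contrast and contrast sources,
for each discretization.  The residual sums are taken over complex moduli
(the only reading under which $\eta$ is a norm); residuals are reported
per transmitter and aggregated, since the original tabulation does not
say which was used.  `stroke_stats()` converts a reconstruction back to
$(\epsilon_r, \sigma)$ and reports region means, standard deviations,
maxima and the percentage of cells above detection thresholds (defaults
$\epsilon_r > 53$, $\sigma > 1$ S/m).  `convergence_report()` assembles
per-iteration cost logs for log-scale overlay across discretizations.

# Numerical choices and defaults

| parameter | default | rationale |
|---|---|---|
| frequency | 1 GHz | penetration/resolution trade-off for head imaging |
| box size | 140 mm | keeps the outer boundary > λ/4 beyond the head in the coupling medium |
| mesh size (inversion / data) | 5 mm / 4 mm | ~9–13 points per wavelength; distinct meshes avoid the inverse crime |
| ABC | first order, impedance $jk_b$ | the boundary condition's order is a modelling choice; first order suffices at these stand-off distances |
| solver tolerance | 1e-12 relative | leaves the exact-consistency residual dominated by the discretization, not the solver |
| CSI iterations | 100 | convergence plateau on the packaged scenarios |
| static pivot threshold | 1e-14 relative | perturbation magnitude recovered by one refinement step |
| noise | none (option: SNR dB + seed) | reference runs are noiseless |

Degenerate inputs are rejected loudly: zero-volume cells name the cell,
non-closed boundary surfaces abort the boundary assembly, empty regions
abort the statistics, an all-zero dataset aborts backpropagation, and a
zero contrast sends `cost_FD()` to an error that points at
backpropagation initialization.

# Problem sizes used by the tests

The test suite exercises the full chain at desk scale: element-level
oracles on single random tetrahedra; forward-solver and dipole-field
convergence checks on 80–120 mm boxes at 5–20 mm resolution; the
low-contrast recovery scenario (35 mm phantom, 8 antennas, 12 mm data /
15 mm inversion meshes, contrast magnitude below 0.8) for 25–100 CSI
iterations; and the reference head fixture (140 mm box, 5 mm mesh,
160,804 edges, 4 antennas) for the consistency experiments.  These sizes
were chosen so the whole suite runs in minutes on one CPU while keeping
every wavelength-resolution ratio in the regime the method is designed
for.

# Known limitations

* Structured box meshes only are generated internally; unstructured
  tetrahedral meshes can be imported (Gmsh MSH 2.2) and assembled, but the
  fast point location and the nested interpolation utility need the
  structured grid.
* The port model is an idealized annular aperture; no antenna CAD, feed
  network, or calibration chain.
* Single frequency per run; no dispersion models, no multi-frequency
  inversion, no regularization term (a hook exists in the configuration).
* The CSI method itself under-estimates high contrasts; the low-contrast
  recovery tests reflect the regime where quantitative recovery is
  expected.
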