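/* Gene circuit right-hand side for deSolve's compiled-model interface.
 *
 * State layout: y[a*N + i] = concentration of gene a in nucleus i
 * (gene-major, N nuclei per gene).
 *
 * Parameter vector layout (padded to PARMS_LEN doubles):
 *   p[0] G  number of gap genes
 *   p[1] N  number of nuclei
 *   p[2] M  number of external inputs
 *   p[3] synthesis flag (0 during mitosis)
 *   p[4] diffusion scale 4^n for n prior divisions
 *   p[5 ...]                R[G], D[G], lambda[G], h[G]
 *   then W[G*G] column-major with W[a + G*b] = weight of regulator b on
 *   target a, then E[G*M] with E[a + G*m].
 *   then Tn, tgrid[Tn], V[Tn*M*N] external input concentrations with
 *   V[k*M*N + m*N + i]; inputs are linearly interpolated in t between
 *   grid points (constant extrapolation outside the grid).
 *
 * The fixed-length copy is the standard deSolve idiom for variable-size
 * models; unused tail entries are ignored.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define PARMS_LEN 32768

static double p[PARMS_LEN];

void circuit_init(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, p);
}

void circuit_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const int G = (int) p[0];
    const int N = (int) p[1];
    const int M = (int) p[2];
    const int syn = (int) p[3];
    const double Ds = p[4];
    const double *R = p + 5;
    const double *D = R + G;
    const double *lam = D + G;
    const double *h = lam + G;
    const double *W = h + G;
    const double *E = W + G * G;
    const double *rest = E + G * M;
    const int Tn = (int) rest[0];
    const double *tg = rest + 1;
    const double *V = tg + Tn;
    const double *V0, *V1;
    double w1 = 0.0;
    int a, b, i, m, k = 0;

    if (Tn >= 2) {
        double tt = *t;
        if (tt <= tg[0]) {
            k = 0; w1 = 0.0;
        } else if (tt >= tg[Tn - 1]) {
            k = Tn - 2; w1 = 1.0;
        } else {
            while (k < Tn - 2 && tg[k + 1] < tt) k++;
            double dt = tg[k + 1] - tg[k];
            w1 = dt > 0.0 ? (tt - tg[k]) / dt : 0.0;
        }
    }
    V0 = V + (size_t) k * M * N;
    V1 = V + (size_t) (k + 1) * M * N;

    for (a = 0; a < G; a++) {
        const double Da = D[a] * Ds;
        const double la = lam[a];
        for (i = 0; i < N; i++) {
            const double v = y[a * N + i];
            double s = 0.0, diff = 0.0;
            if (syn) {
                double u = h[a];
                for (b = 0; b < G; b++)
                    u += W[a + G * b] * y[b * N + i];
                for (m = 0; m < M; m++) {
                    const double vm = V0[m * N + i] * (1.0 - w1)
                        + V1[m * N + i] * w1;
                    u += E[a + G * m] * vm;
                }
                s = R[a] * 0.5 * (u / sqrt(u * u + 1.0) + 1.0);
            }
            if (i > 0)     diff += y[a * N + i - 1] - v;
            if (i < N - 1) diff += y[a * N + i + 1] - v;
            ydot[a * N + i] = s + Da * diff - la * v;
        }
    }
}

static const R_CMethodDef cMethods[] = {
    {"circuit_derivs", (DL_FUNC) &circuit_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_gapCircuits(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
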