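/* Whole-body perfusion-limited PBPK right-hand side for deSolve.
 *
 * States (amounts, ug):
 *   y[0..11]  tissues: lung, heart, brain, muscle, adipose, skin, bone,
 *             liver, gut, spleen, kidney, rest-of-body
 *   y[12]     arterial blood
 *   y[13]     venous blood
 *   y[14]     gut lumen depot (oral)
 *   y[15]     cumulative eliminated (audit state)
 *
 * Parameters (all flows L/h, volumes L, clearances L/h):
 *   p[0..11]  regional blood flows (lung row = cardiac output)
 *   p[12..23] tissue volumes
 *   p[24..35] R_t = B:P / Kp_t (tissue outflow blood conc = C_t * R_t)
 *   p[36] V_arterial  p[37] V_venous
 *   p[38] hepatic unbound intrinsic clearance fu_b*CLint (applied to liver
 *         outflow blood concentration)
 *   p[39] renal plasma clearance (applied to arterial plasma)
 *   p[40] blood:plasma ratio
 *   p[41] ka (1/h)   p[42] oral flag (0/1)
 *   p[43] infusion rate (ug/h)  p[44] infusion duration (h)
 *   p[45] number of doses       p[46] dosing interval (h)
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define NPAR 47

static double p[NPAR];

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const int LUNG = 0, LIVER = 7, GUT = 8, SPLEEN = 9, KIDNEY = 10;
    double Cv[12];
    double Cart = y[12] / p[36];
    double Cven = y[13] / p[37];
    double Qco = p[0];
    double bp = p[40];
    double venous_in = 0.0, sumQ = 0.0;
    int i, k;

    for (i = 0; i < 12; i++)
        Cv[i] = y[i] / p[12 + i] * p[24 + i];

    /* lung: receives total venous return */
    ydot[LUNG] = Qco * (Cven - Cv[LUNG]);

    /* simple systemic tissues draining to the venous pool */
    for (i = 1; i < 12; i++) {
        if (i == LIVER || i == GUT || i == SPLEEN || i == KIDNEY) continue;
        ydot[i] = p[i] * (Cart - Cv[i]);
        venous_in += p[i] * Cv[i];
    }

    /* splanchnic organs drain into the portal vein (-> liver) */
    ydot[GUT] = p[GUT] * (Cart - Cv[GUT]);
    ydot[SPLEEN] = p[SPLEEN] * (Cart - Cv[SPLEEN]);

    /* liver: arterial + portal inflow, first-order oral absorption into the
     * portal stream, well-stirred elimination on outflow blood conc. */
    {
        double Qout = p[LIVER] + p[GUT] + p[SPLEEN];
        double absorb = (p[42] > 0.5) ? p[41] * y[14] : 0.0;
        ydot[LIVER] = p[LIVER] * Cart + p[GUT] * Cv[GUT] +
            p[SPLEEN] * Cv[SPLEEN] + absorb -
            Qout * Cv[LIVER] - p[38] * Cv[LIVER];
        venous_in += Qout * Cv[LIVER];
    }

    /* kidney: renal clearance drawn from arterial plasma */
    ydot[KIDNEY] = p[KIDNEY] * (Cart - Cv[KIDNEY]) - p[39] * Cart / bp;
    venous_in += p[KIDNEY] * Cv[KIDNEY];

    for (i = 1; i < 12; i++) sumQ += p[i];

    ydot[12] = Qco * Cv[LUNG] - sumQ * Cart;

    /* IV infusion input (possibly repeated doses) into the venous pool */
    {
        double rate = 0.0;
        if (p[42] < 0.5) {
            int nd = (int) (p[45] + 0.5);
            for (k = 0; k < nd; k++) {
                double t0 = k * p[46];
                if (*t >= t0 && *t < t0 + p[44]) rate += p[43];
            }
        }
        ydot[13] = venous_in - Qco * Cven + rate;
    }

    /* oral depot */
    ydot[14] = (p[42] > 0.5) ? -p[41] * y[14] : 0.0;

    /* cumulative elimination audit */
    ydot[15] = p[38] * Cv[LIVER] + p[39] * Cart / bp;
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_cirrhPBPK(DllInfo *info)
{
    R_registerRoutines(info, cMethods, NULL, NULL, NULL);
    /* deSolve looks the symbols up by name */
    R_useDynamicSymbols(info, TRUE);
}
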